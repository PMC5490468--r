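# Substitution matrices: bundled NCBI PAM/BLOSUM tables, custom-matrix
# parsing, the master-file format binding matrices to gap penalties, the
# log-odds construction s_ij = ln(q_ij / (p_i p_j)) / lambda, and the
# conservative / non-conservative call derived from the score sign.

PREDEFINED_MATRICES <- c("PAM30", "PAM40", "PAM70", "PAM120", "PAM250",
                         "BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                         "BLOSUM100")

#' Construct a substitution matrix
#'
#' @param scores Square numeric matrix with identical row/column names (the
#'   residue alphabet), holding log-odds scores.
#' @param label Display label.
#' @param symmetrize If `TRUE`, asymmetric input is symmetrized by averaging
#'   instead of rejected.
#' @param tol Symmetry tolerance.
#' @return Object of class `substitution_matrix`: a numeric matrix with a
#'   `label` attribute.
#' @export
substitution_matrix <- function(scores, label = "custom",
                                symmetrize = FALSE, tol = 1e-9) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    mc_input_error("scores must be a numeric matrix")
  }
  if (nrow(scores) != ncol(scores)) {
    mc_input_error(sprintf("matrix '%s' is not square (%d rows, %d columns)",
                           label, nrow(scores), ncol(scores)))
  }
  rn <- rownames(scores); cn <- colnames(scores)
  if (is.null(rn) || is.null(cn)) {
    mc_input_error(sprintf("matrix '%s' must carry residue row and column names", label))
  }
  if (!identical(rn, cn)) {
    mc_input_error(sprintf(
      "matrix '%s': row labels (%s...) do not match column labels (%s...)",
      label, paste(utils::head(rn, 3), collapse = ","),
      paste(utils::head(cn, 3), collapse = ",")))
  }
  if (anyDuplicated(rn)) {
    mc_input_error(sprintf("matrix '%s': duplicated residue label '%s'",
                           label, rn[duplicated(rn)][1L]))
  }
  if (any(!is.finite(scores))) {
    bad <- which(!is.finite(scores), arr.ind = TRUE)[1L, ]
    mc_input_error(sprintf("matrix '%s': non-numeric value at row %s, column %s",
                           label, rn[bad[1L]], cn[bad[2L]]))
  }
  asym <- abs(scores - t(scores))
  if (max(asym) > tol) {
    if (symmetrize) {
      scores <- (scores + t(scores)) / 2
    } else {
      bad <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
      mc_input_error(sprintf(
        "matrix '%s' is asymmetric: score(%s,%s)=%g but score(%s,%s)=%g",
        label, rn[bad[1L]], cn[bad[2L]], scores[bad[1L], bad[2L]],
        cn[bad[2L]], rn[bad[1L]], scores[bad[2L], bad[1L]]))
    }
  }
  structure(scores, label = label, class = c("substitution_matrix", "matrix", "array"))
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat(sprintf("substitution_matrix '%s': %d x %d over {%s}\n",
              attr(x, "label"), nrow(x), ncol(x),
              paste(rownames(x), collapse = "")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @rdname substitution_matrix
#' @param x Object to test.
#' @export
is_substitution_matrix <- function(x) inherits(x, "substitution_matrix")

#' Names of the bundled substitution matrices
#' @return Character vector of the ten predefined PAM/BLOSUM names.
#' @export
predefined_matrix_names <- function() PREDEFINED_MATRICES

#' Load a bundled PAM or BLOSUM matrix
#'
#' The package ships PAM30/40/70/120/250 and BLOSUM45/50/62/80/100 with
#' NCBI-standard integer values as plain-text data files.
#'
#' @param name One of [predefined_matrix_names()].
#' @return A [substitution_matrix()].
#' @export
load_predefined <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !toupper(name) %in% PREDEFINED_MATRICES) {
    mc_input_error(sprintf(
      "unknown predefined matrix '%s'; available: %s",
      as.character(name)[1L], paste(PREDEFINED_MATRICES, collapse = ", ")))
  }
  name <- toupper(name)
  path <- system.file("extdata", "matrices", paste0(name, ".txt"),
                      package = "matcompare", mustWork = TRUE)
  read_matrix_file(path, label = name)
}

#' Parse a substitution matrix from space-delimited text
#'
#' Dialect (NCBI flat layout): `#`-prefixed comment lines are ignored; the
#' first data row is the column alphabet; every following row starts with its
#' residue label followed by one numeric cell per column. Real (non-integer)
#' values are allowed.
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   lines.
#' @param label Label for the resulting matrix.
#' @param symmetrize Average out asymmetries instead of failing.
#' @return A [substitution_matrix()].
#' @export
parse_matrix_text <- function(text, label = "custom", symmetrize = FALSE) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- sub("\r$", "", text)
  lines <- lines[!grepl("^[ \t]*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    mc_input_error(sprintf("matrix '%s': no parsable rows", label))
  }
  toks <- strsplit(trimws(lines), "[ \t]+")
  alphabet <- toupper(toks[[1L]])
  n <- length(alphabet)
  body <- toks[-1L]
  if (length(body) != n) {
    mc_input_error(sprintf(
      "matrix '%s' is not square: header declares %d residues but %d rows follow",
      label, n, length(body)))
  }
  scores <- matrix(NA_real_, n, n, dimnames = list(alphabet, alphabet))
  row_labels <- character(n)
  for (k in seq_len(n)) {
    row <- body[[k]]
    row_labels[k] <- toupper(row[1L])
    if (length(row) - 1L != n) {
      mc_input_error(sprintf(
        "matrix '%s': row '%s' has %d cells, expected %d",
        label, row[1L], length(row) - 1L, n))
    }
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      mc_input_error(sprintf(
        "matrix '%s': non-numeric cell '%s' in row '%s', column %s",
        label, row[-1L][j], row[1L], alphabet[j]))
    }
    scores[k, ] <- vals
  }
  if (!identical(row_labels, alphabet)) {
    bad <- which(row_labels != alphabet)[1L]
    mc_input_error(sprintf(
      "matrix '%s': row label '%s' does not match column label '%s' at position %d",
      label, row_labels[bad], alphabet[bad], bad))
  }
  rownames(scores) <- row_labels
  substitution_matrix(scores, label = label, symmetrize = symmetrize)
}

#' Read a substitution matrix from a file
#' @param path Path to a space-delimited matrix file.
#' @inheritParams parse_matrix_text
#' @return A [substitution_matrix()].
#' @export
read_matrix_file <- function(path, label = NULL, symmetrize = FALSE) {
  if (!file.exists(path)) {
    mc_input_error(sprintf("matrix file not found: '%s'", path))
  }
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  parse_matrix_text(readLines(path, warn = FALSE), label = label,
                    symmetrize = symmetrize)
}

#' Bind a matrix to gap penalties
#'
#' Penalties follow the sign convention of the master-file format: they are
#' non-positive numbers *added* to the score. A gap run of length L costs
#' `gap_open + L * gap_extend` (the first gap residue pays both). Positive
#' inputs are negated with a warning.
#'
#' @param matrix A [substitution_matrix()].
#' @param gap_open Gap opening penalty (<= 0).
#' @param gap_extend Gap extension penalty per gap column (<= 0).
#' @param label Unique configuration label (e.g. "CM0", "PAM70").
#' @return Object of class `matrix_config`.
#' @export
matrix_config <- function(matrix, gap_open, gap_extend, label = NULL) {
  if (!is_substitution_matrix(matrix)) {
    mc_input_error("matrix must be a substitution_matrix")
  }
  if (!is_scalar_number(gap_open) || !is_scalar_number(gap_extend)) {
    mc_input_error("gap_open and gap_extend must be finite numbers")
  }
  if (gap_open > 0) {
    warning(sprintf("gap_open %g is positive; negating (penalties are added to the score)",
                    gap_open), call. = FALSE)
    gap_open <- -gap_open
  }
  if (gap_extend > 0) {
    warning(sprintf("gap_extend %g is positive; negating", gap_extend), call. = FALSE)
    gap_extend <- -gap_extend
  }
  if (is.null(label)) label <- attr(matrix, "label")
  structure(
    list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         label = label),
    class = "matrix_config"
  )
}

#' @export
print.matrix_config <- function(x, ...) {
  cat(sprintf("matrix_config %s: %s (gap %g, extension %g)\n",
              x$label, attr(x$matrix, "label"), x$gap_open, x$gap_extend))
  invisible(x)
}

#' Parse a custom-matrix master file
#'
#' Each non-empty line names one matrix file followed by its space-delimited
#' gap and extension penalties; the same filename may repeat with different
#' penalties to explore penalty effects. Filenames are resolved relative to
#' the master file's directory. Configurations are labelled "CM0", "CM1", ...
#' in file order.
#'
#' @param path Path to the master file (`NULL`/missing path yields the
#'   dedicated "no master file" error so callers can surface the custom-matrix
#'   option being enabled without a file).
#' @param symmetrize Passed to the matrix parser.
#' @return List of [matrix_config()] objects.
#' @export
parse_master_file <- function(path, symmetrize = FALSE) {
  if (is.null(path) || !length(path) || !nzchar(path)) {
    mc_input_error(
      "custom matrix option is enabled but no master file listing the matrices was given")
  }
  if (!file.exists(path)) {
    mc_input_error(sprintf("master file not found: '%s'", path))
  }
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[!grepl("^[ \t]*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning(sprintf("master file '%s' lists no matrices", path), call. = FALSE)
    return(list())
  }
  base <- dirname(normalizePath(path))
  cache <- new.env(parent = emptyenv())
  configs <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    toks <- strsplit(trimws(lines[k]), "[ \t]+")[[1L]]
    if (length(toks) < 3L) {
      mc_input_error(sprintf(
        "missing penalties in master file line %d ('%s'): expected 'filename gap_open gap_extend'",
        k, lines[k]))
    }
    if (length(toks) > 3L) {
      mc_input_error(sprintf(
        "master file line %d has %d fields; expected 'filename gap_open gap_extend'",
        k, length(toks)))
    }
    pen <- suppressWarnings(as.numeric(toks[2:3]))
    if (anyNA(pen)) {
      mc_input_error(sprintf("non-numeric penalty in master file line %d ('%s')",
                             k, lines[k]))
    }
    mfile <- toks[1L]
    mpath <- if (grepl("^(/|~|[A-Za-z]:)", mfile)) mfile else file.path(base, mfile)
    if (!file.exists(mpath)) {
      mc_input_error(sprintf(
        "custom matrix file '%s' (master file line %d) not found", mfile, k))
    }
    key <- normalizePath(mpath)
    if (is.null(cache[[key]])) {
      cache[[key]] <- read_matrix_file(mpath, symmetrize = symmetrize)
    }
    configs[[k]] <- matrix_config(cache[[key]], pen[1L], pen[2L],
                                  label = paste0("CM", k - 1L))
  }
  configs
}

#' Look up a log-odds score
#'
#' @param matrix A [substitution_matrix()].
#' @param a,b Single residue codes.
#' @param lenient If `TRUE`, a residue missing from the matrix alphabet scores
#'   0 with a warning instead of failing.
#' @return The log-odds score `s_ab` (symmetric in `a`, `b`).
#' @export
lookup_score <- function(matrix, a, b, lenient = FALSE) {
  if (!is_substitution_matrix(matrix)) {
    mc_input_error("matrix must be a substitution_matrix")
  }
  for (r in c(a, b)) {
    if (!is.character(r) || length(r) != 1L || nchar(r) != 1L) {
      mc_input_error("residues must be single characters")
    }
    if (r == GAP_CHAR) {
      mc_input_error("log-odds score is undefined for gap characters")
    }
  }
  a <- toupper(a); b <- toupper(b)
  ab <- rownames(matrix)
  if (!(a %in% ab) || !(b %in% ab)) {
    missing_res <- if (a %in% ab) b else a
    if (lenient) {
      warning(sprintf("residue '%s' not in matrix '%s' alphabet; scoring 0",
                      missing_res, attr(matrix, "label")), call. = FALSE)
      return(0)
    }
    mc_input_error(sprintf("residue '%s' not in alphabet of matrix '%s'",
                           missing_res, attr(matrix, "label")))
  }
  unname(matrix[a, b])
}

#' Classify a substitution as conservative or not
#'
#' A substitution with positive log-odds score is conservative, a negative
#' score is non-conservative; a score of exactly zero is reported as its own
#' "neutral" class rather than silently binned with either side.
#'
#' @inheritParams lookup_score
#' @return One of `"conservative"`, `"non_conservative"`, `"neutral"`.
#' @export
conservation_call <- function(matrix, a, b, lenient = FALSE) {
  s <- lookup_score(matrix, a, b, lenient = lenient)
  if (s > 0) "conservative" else if (s < 0) "non_conservative" else "neutral"
}

#' Frequency model behind a log-odds matrix
#'
#' @param q Symmetric matrix of observed pair frequencies `q_ij` in (0, 1].
#' @param p Named vector of background frequencies `p_i` in (0, 1].
#' @param lambda Positive scaling constant.
#' @return Object of class `frequency_model`.
#' @export
frequency_model <- function(q, p, lambda) {
  if (!is.matrix(q) || !is.numeric(q) || nrow(q) != ncol(q)) {
    mc_input_error("q must be a square numeric matrix")
  }
  ab <- rownames(q)
  if (is.null(ab) || !identical(ab, colnames(q))) {
    mc_input_error("q must carry identical residue row/column names")
  }
  if (is.null(names(p))) names(p) <- ab
  if (!identical(sort(names(p)), sort(ab))) {
    mc_input_error("p must provide a background frequency for every residue in q")
  }
  p <- p[ab]
  if (any(q <= 0) || any(q > 1)) {
    mc_input_error("all pair frequencies q_ij must lie in (0, 1]")
  }
  if (any(p <= 0) || any(p > 1)) {
    mc_input_error("all background frequencies p_i must lie in (0, 1]")
  }
  if (max(abs(q - t(q))) > 1e-12) mc_input_error("q must be symmetric")
  if (!is_scalar_number(lambda) || lambda <= 0) {
    mc_input_error("lambda must be a positive number")
  }
  structure(list(q = q, p = p, lambda = lambda), class = "frequency_model")
}

#' Build a log-odds matrix from a frequency model
#'
#' Computes `s_ij = ln(q_ij / (p_i p_j)) / lambda` for every ordered residue
#' pair. When observed pair frequencies equal the chance expectation
#' (`q_ij = p_i p_j`) every score is zero; doubling `lambda` halves every
#' score.
#'
#' @param model A [frequency_model()].
#' @param label Label for the resulting matrix.
#' @return A [substitution_matrix()].
#' @export
log_odds_matrix <- function(model, label = "log-odds") {
  if (!inherits(model, "frequency_model")) {
    mc_input_error("model must be a frequency_model")
  }
  expected <- outer(model$p, model$p)
  s <- log(model$q / expected) / model$lambda
  substitution_matrix(s, label = label)
}
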