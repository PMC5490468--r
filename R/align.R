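# Affine-gap pairwise alignment of a protein pattern against a subject.
#
# Three-state Gotoh dynamic programming (match / gap-in-subject /
# gap-in-pattern) with mode-specific initialisation and traceback origin.
# Full DP matrices are kept: inputs are protein-scale and the contract is
# optimality, not speed. A gap run of length L costs gap_open + L*gap_extend
# (both penalties non-positive and added to the score; the first gap column
# pays both).
#
# The five modes:
#   global       - both sequences aligned end to end, terminal gaps charged
#                  (Needleman-Wunsch).
#   local        - best-scoring pair of substrings, score floored at 0
#                  (Smith-Waterman); a zero optimum yields an empty alignment.
#   overlap      - both sequences fully spanned but the leading and trailing
#                  gap run cost nothing (ends-free).
#   global_local - the WHOLE pattern aligned against some contiguous
#                  substring of the subject (subject ends clipped, free).
#   local_global - the WHOLE subject aligned against some contiguous
#                  substring of the pattern.
# The two mixed modes are easily confused: the sequence named first in the
# mode is the one aligned in full.

ALIGNMENT_MODES <- c("global", "local", "overlap", "global_local", "local_global")

#' Construct an alignment object
#'
#' Mainly useful for tests and for re-hydrating serialized alignments; normal
#' use produces alignments via [align_pair()].
#'
#' @param aligned_pattern,aligned_subject Equal-length gapped strings
#'   (gap character `-`); no column may be gap/gap.
#' @param score Alignment score.
#' @param mode One of the five alignment modes.
#' @param config_label Label of the scoring configuration.
#' @param pattern_range,subject_range 1-based closed intervals of original
#'   sequence positions covered (`c(NA, NA)` for an empty local alignment).
#' @param pattern_length,subject_length Ungapped lengths of the ORIGINAL
#'   input sequences (used by PID3/PID4); default to the degapped aligned
#'   strings.
#' @return Object of class `pairwise_alignment`.
#' @export
new_alignment <- function(aligned_pattern, aligned_subject, score = NA_real_,
                          mode = "global", config_label = "manual",
                          pattern_range = NULL, subject_range = NULL,
                          pattern_length = NULL, subject_length = NULL) {
  mode <- match.arg(mode, ALIGNMENT_MODES)
  if (!is.character(aligned_pattern) || !is.character(aligned_subject) ||
      length(aligned_pattern) != 1L || length(aligned_subject) != 1L) {
    mc_input_error("aligned strings must be single character values")
  }
  if (nchar(aligned_pattern) != nchar(aligned_subject)) {
    mc_input_error("aligned pattern and subject must have equal length")
  }
  if (nchar(aligned_pattern) == 0L && mode != "local") {
    mc_input_error("only local alignments may be empty")
  }
  pc <- chars(aligned_pattern); sc <- chars(aligned_subject)
  if (any(pc == GAP_CHAR & sc == GAP_CHAR)) {
    mc_input_error("alignment contains a gap/gap column")
  }
  np <- nchar(degap(aligned_pattern)); ns <- nchar(degap(aligned_subject))
  if (is.null(pattern_range)) pattern_range <- if (np) c(1L, np) else c(NA_integer_, NA_integer_)
  if (is.null(subject_range)) subject_range <- if (ns) c(1L, ns) else c(NA_integer_, NA_integer_)
  if (is.null(pattern_length)) pattern_length <- np
  if (is.null(subject_length)) subject_length <- ns
  structure(
    list(aligned_pattern = aligned_pattern, aligned_subject = aligned_subject,
         score = score, mode = mode, config_label = config_label,
         pattern_range = as.integer(pattern_range),
         subject_range = as.integer(subject_range),
         pattern_length = as.integer(pattern_length),
         subject_length = as.integer(subject_length)),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment [%s, %s] score %.4g\n",
              x$mode, x$config_label, x$score))
  if (nchar(x$aligned_pattern)) {
    w <- 60L
    starts <- seq(1L, nchar(x$aligned_pattern), by = w)
    for (s in starts) {
      cat("  P: ", substr(x$aligned_pattern, s, s + w - 1L), "\n",
          "  S: ", substr(x$aligned_subject, s, s + w - 1L), "\n", sep = "")
    }
  } else {
    cat("  (empty alignment)\n")
  }
  invisible(x)
}

#' @noRd
alignment_length <- function(alignment) nchar(alignment$aligned_pattern)

# Resolve sequences/config inputs shared by align_pair and the oracle.
#' @noRd
prepare_alignment_problem <- function(pattern, subject, config, lenient = FALSE) {
  as_residues <- function(x, what) {
    if (inherits(x, "protein_sequence")) return(x$residues)
    if (is.character(x) && length(x) == 1L) {
      return(validate_residues(x, lenient = lenient))
    }
    mc_input_error(sprintf("%s must be a protein_sequence or residue string", what))
  }
  if (!inherits(config, "matrix_config")) {
    if (is_substitution_matrix(config)) {
      config <- matrix_config(config, gap_open = -10, gap_extend = -4)
    } else {
      mc_input_error("config must be a matrix_config (or substitution_matrix)")
    }
  }
  p <- as_residues(pattern, "pattern")
  s <- as_residues(subject, "subject")
  if (!nchar(p) || !nchar(s)) mc_input_error("sequences must be non-empty")
  mat <- config$matrix
  ab <- rownames(mat)
  pc <- chars(p); sc <- chars(s)
  pidx <- match(pc, ab); sidx <- match(sc, ab)
  if (!lenient && (anyNA(pidx) || anyNA(sidx))) {
    bad <- c(pc[is.na(pidx)], sc[is.na(sidx)])[1L]
    mc_align_error(sprintf(
      "alignment failed for '%s': residue '%s' is absent from the substitution matrix (poorly constructed sequences or custom matrices)",
      config$label, bad))
  }
  # Substitution score table S[i, j] = score(p_i, s_j); unknown residues
  # score 0 in lenient mode.
  S <- matrix(0, length(pc), length(sc))
  okp <- which(!is.na(pidx)); oks <- which(!is.na(sidx))
  if (length(okp) && length(oks)) {
    S[okp, oks] <- unclass(mat)[pidx[okp], sidx[oks], drop = FALSE]
  }
  list(p = pc, s = sc, S = S, config = config,
       open = config$gap_open, ext = config$gap_extend)
}

# Fill the three DP matrices. Cell (i+1, j+1) = i pattern and j subject
# residues consumed. Returns list(M, X, Y); X = gap in subject (consumes
# pattern), Y = gap in pattern (consumes subject).
#' @noRd
gotoh_fill <- function(S, open, ext, mode) {
  n <- nrow(S); m <- ncol(S)
  M <- matrix(-Inf, n + 1L, m + 1L)
  X <- matrix(-Inf, n + 1L, m + 1L)
  Y <- matrix(-Inf, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  # Mode-specific borders.
  if (mode == "global") {
    Y[1L, 2L:(m + 1L)] <- open + (1:m) * ext
  } else if (mode == "overlap") {
    Y[1L, 2L:(m + 1L)] <- 0
  } else if (mode == "global_local") {
    M[1L, ] <- 0                      # clip subject prefix for free
    Y[1L, 2L:(m + 1L)] <- open + ext  # charged gap-in-pattern after any clip
  } else if (mode == "local_global") {
    M[, 1L] <- 0                      # clip pattern prefix for free
    Y[1L, 2L:(m + 1L)] <- open + (1:m) * ext
  } else if (mode == "local") {
    M[, 1L] <- 0
    M[1L, ] <- 0
  }
  for (i in seq_len(n)) {
    r <- i + 1L
    prevM <- M[r - 1L, ]; prevX <- X[r - 1L, ]; prevY <- Y[r - 1L, ]
    mrow <- pmax(prevM[1:m], prevX[1:m], prevY[1:m]) + S[i, ]
    if (mode == "local") mrow <- pmax(mrow, 0)
    M[r, 2L:(m + 1L)] <- mrow
    X[r, ] <- pmax(prevM + open + ext, prevX + ext, prevY + open + ext)
    if (mode == "overlap") X[r, 1L] <- 0
    # Gap-in-pattern row: Y[r, u] = max over gap starts; linear scan done
    # with a cummax trick (run of length L from source k costs open + L*ext).
    G <- pmax(M[r, 1:m], X[r, 1:m])
    src <- c(Y[r, 1L], G + open - (0:(m - 1L)) * ext)
    cm <- cummax(src)
    Y[r, 2L:(m + 1L)] <- (1:m) * ext + cm[2L:(m + 1L)]
  }
  list(M = M, X = X, Y = Y)
}

# Pick the traceback origin (alignment end cell + state) for a mode.
# States are preferred M (diagonal) > X (gap-in-subject) > Y, and among
# equal-scoring cells the earliest one in the stated scan order wins.
#' @noRd
pick_origin <- function(dp, mode, n, m) {
  states <- c("M", "X", "Y")
  best <- list(score = -Inf, i = NA_integer_, j = NA_integer_, state = NA_character_)
  consider <- function(i, j) {
    for (st in states) {
      v <- dp[[st]][i + 1L, j + 1L]
      if (v > best$score + 1e-12) {
        best <<- list(score = v, i = i, j = j, state = st)
      }
    }
  }
  if (mode == "global") {
    consider(n, m)
  } else if (mode == "overlap") {
    for (i in 0:(n - 1L)) consider(i, m)
    for (j in 0:m) consider(n, j)
  } else if (mode == "global_local") {
    for (j in 0:m) consider(n, j)
  } else if (mode == "local_global") {
    for (i in 0:n) consider(i, m)
  } else if (mode == "local") {
    # column-major scan: ties resolve to the smallest subject position,
    # then the smallest pattern position
    Mm <- dp$M
    k <- which.max(Mm)
    best <- list(score = Mm[k],
                 i = (k - 1L) %% (n + 1L),
                 j = (k - 1L) %/% (n + 1L),
                 state = "M")
    if (best$score <= 1e-12) {
      best <- list(score = 0, i = 0L, j = 0L, state = "empty")
    }
  }
  best
}

# Trace one optimal path back from (i, j, state). Returns the alignment
# columns (in order) and the stop coordinates.
#' @noRd
gotoh_traceback <- function(dp, S, p, s, open, ext, mode, i, j, state) {
  M <- dp$M; X <- dp$X; Y <- dp$Y
  pcol <- character(0); scol <- character(0)  # built back-to-front
  near <- function(a, b) {
    is.finite(a) && is.finite(b) && abs(a - b) <= 1e-9 * max(1, abs(a), abs(b))
  }
  pick_state <- function(target, cand) {
    for (st in c("M", "X", "Y")) if (near(cand[[st]], target)) return(st)
    stop("internal error: traceback lost the optimal path")  # nocov
  }
  repeat {
    if (state == "M") {
      val <- M[i + 1L, j + 1L]
      if (i == 0L && j == 0L) break
      if (mode == "global_local" && i == 0L) break
      if (mode == "local_global" && j == 0L) break
      if (mode == "local" && val <= 1e-12) break
      target <- val - S[i, j]
      st <- pick_state(target, list(M = M[i, j], X = X[i, j], Y = Y[i, j]))
      pcol <- c(p[i], pcol); scol <- c(s[j], scol)
      i <- i - 1L; j <- j - 1L; state <- st
      if (mode == "local" && state == "M" && M[i + 1L, j + 1L] <= 1e-12) break
    } else if (state == "X") {
      if (j == 0L) {  # border: pattern prefix against gaps
        pcol <- c(p[seq_len(i)], pcol); scol <- c(rep(GAP_CHAR, i), scol)
        i <- 0L
        break
      }
      target <- X[i + 1L, j + 1L]
      st <- pick_state(target, list(M = M[i, j + 1L] + open + ext,
                                    X = X[i, j + 1L] + ext,
                                    Y = Y[i, j + 1L] + open + ext))
      pcol <- c(p[i], pcol); scol <- c(GAP_CHAR, scol)
      i <- i - 1L; state <- st
      if (mode == "local" && state == "M" && M[i + 1L, j + 1L] <= 1e-12) break
    } else {  # Y
      if (i == 0L) {  # border: subject prefix against gaps
        pcol <- c(rep(GAP_CHAR, j), pcol); scol <- c(s[seq_len(j)], scol)
        j <- 0L
        break
      }
      target <- Y[i + 1L, j + 1L]
      st <- pick_state(target, list(M = M[i + 1L, j] + open + ext,
                                    X = X[i + 1L, j] + open + ext,
                                    Y = Y[i + 1L, j] + ext))
      pcol <- c(GAP_CHAR, pcol); scol <- c(s[j], scol)
      j <- j - 1L; state <- st
      if (mode == "local" && state == "M" && M[i + 1L, j + 1L] <= 1e-12) break
    }
  }
  list(pcol = pcol, scol = scol, i0 = i, j0 = j)
}

#' Align a pattern/subject pair under one scoring configuration
#'
#' Computes an optimal affine-gap pairwise alignment for the requested mode
#' and returns one optimal alignment with deterministic tie-breaking
#' (diagonal preferred over gap-in-subject over gap-in-pattern; earliest
#' origin among equal-scoring cells).
#'
#' @param pattern,subject [protein_sequence()] objects or residue strings.
#' @param config A [matrix_config()] (or bare [substitution_matrix()], which
#'   gets default penalties -10/-4).
#' @param mode One of `"global"`, `"local"`, `"overlap"`, `"global_local"`,
#'   `"local_global"`.
#' @param lenient Score residues missing from the matrix alphabet as 0
#'   instead of failing.
#' @return A [new_alignment()] object carrying the optimal score, the gapped
#'   strings, and 1-based closed coordinate ranges on the original sequences.
#' @export
align_pair <- function(pattern, subject, config,
                       mode = c("global", "local", "overlap",
                                "global_local", "local_global"),
                       lenient = FALSE) {
  mode <- match.arg(mode)
  prob <- prepare_alignment_problem(pattern, subject, config, lenient = lenient)
  n <- length(prob$p); m <- length(prob$s)
  dp <- gotoh_fill(prob$S, prob$open, prob$ext, mode)
  org <- pick_origin(dp, mode, n, m)
  label <- prob$config$label

  if (identical(org$state, "empty")) {  # local mode, no positive-scoring pair
    return(new_alignment("", "", score = 0, mode = mode, config_label = label,
                         pattern_range = c(NA_integer_, NA_integer_),
                         subject_range = c(NA_integer_, NA_integer_),
                         pattern_length = n, subject_length = m))
  }

  tb <- gotoh_traceback(dp, prob$S, prob$p, prob$s, prob$open, prob$ext,
                        mode, org$i, org$j, org$state)
  pcol <- tb$pcol; scol <- tb$scol
  # Free trailing gaps for ends-free mode: unconsumed suffixes become gap
  # columns appended after the traceback origin.
  if (mode == "overlap") {
    if (org$i < n) {
      pcol <- c(pcol, prob$p[(org$i + 1L):n])
      scol <- c(scol, rep(GAP_CHAR, n - org$i))
    }
    if (org$j < m) {
      pcol <- c(pcol, rep(GAP_CHAR, m - org$j))
      scol <- c(scol, prob$s[(org$j + 1L):m])
    }
  }
  pattern_range <- switch(mode,
    global = , overlap = , global_local = c(1L, n),
    local_global = , local = c(tb$i0 + 1L, org$i))
  subject_range <- switch(mode,
    global = , overlap = , local_global = c(1L, m),
    global_local = , local = c(tb$j0 + 1L, org$j))
  if (pattern_range[1L] > pattern_range[2L]) pattern_range <- c(NA_integer_, NA_integer_)
  if (subject_range[1L] > subject_range[2L]) subject_range <- c(NA_integer_, NA_integer_)

  new_alignment(paste(pcol, collapse = ""), paste(scol, collapse = ""),
                score = org$score, mode = mode, config_label = label,
                pattern_range = pattern_range, subject_range = subject_range,
                pattern_length = n, subject_length = m)
}

#' Re-score an alignment column by column
#'
#' Independent re-derivation of an alignment's score from its gapped strings:
#' substitution columns are scored through [lookup_score()], every maximal
#' gap run is charged `gap_open + L * gap_extend`, and for overlap mode the
#' leading and trailing gap runs are free. Used to verify that traceback and
#' reported score agree.
#'
#' @param alignment A `pairwise_alignment`.
#' @param config The [matrix_config()] it was computed under.
#' @param lenient Passed to [lookup_score()].
#' @return Numeric score.
#' @export
rescore_alignment <- function(alignment, config, lenient = FALSE) {
  if (!inherits(alignment, "pairwise_alignment")) {
    mc_input_error("alignment must be a pairwise_alignment")
  }
  if (!inherits(config, "matrix_config")) {
    mc_input_error("config must be a matrix_config")
  }
  L <- alignment_length(alignment)
  if (L == 0L) return(0)
  pc <- chars(alignment$aligned_pattern); sc <- chars(alignment$aligned_subject)
  is_gap <- pc == GAP_CHAR | sc == GAP_CHAR
  total <- 0
  for (k in which(!is_gap)) {
    total <- total + lookup_score(config$matrix, pc[k], sc[k], lenient = lenient)
  }
  # maximal gap runs, per aligned string
  runs <- list()
  for (gap_vec in list(pc == GAP_CHAR, sc == GAP_CHAR)) {
    r <- rle(gap_vec)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) runs[[length(runs) + 1L]] <- c(starts[k], ends[k])
  }
  if (length(runs)) {
    runs <- runs[order(vapply(runs, `[`, integer(1), 1L))]
    free_lead <- alignment$mode == "overlap" && runs[[1L]][1L] == 1L
    free_trail <- alignment$mode == "overlap" &&
      runs[[length(runs)]][2L] == L && length(runs) > as.integer(free_lead)
    for (k in seq_along(runs)) {
      if ((k == 1L && free_lead) || (k == length(runs) && free_trail)) next
      len <- runs[[k]][2L] - runs[[k]][1L] + 1L
      total <- total + config$gap_open + len * config$gap_extend
    }
  }
  total
}
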