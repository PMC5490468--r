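# FASTA input/output and residue validation for protein sequences.
#
# A protein_sequence is an identified, validated amino-acid string; in an
# alignment one sequence plays the role of the *pattern* and the other the
# *subject*.

#' Construct a protein sequence
#'
#' @param id Record identifier (FASTA header up to the first whitespace).
#' @param residues Amino-acid string; uppercased and validated.
#' @param description Free-text remainder of the FASTA header.
#' @param lenient If `TRUE`, extended one-letter codes (X, B, Z, U, ...) are
#'   accepted in addition to the 20 standard codes.
#' @return An object of class `protein_sequence` with fields `id`,
#'   `description` and `residues`.
#' @export
protein_sequence <- function(id, residues, description = "", lenient = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    mc_input_error("sequence id must be a non-empty string")
  }
  residues <- validate_residues(residues, lenient = lenient)
  structure(
    list(id = id, description = description, residues = residues),
    class = "protein_sequence"
  )
}

#' @export
print.protein_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  preview <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("protein_sequence %s (%d aa)\n  %s\n", x$id, n, preview))
  invisible(x)
}

#' @export
format.protein_sequence <- function(x, ...) {
  sprintf("%s (%d aa)", x$id, nchar(x$residues))
}

#' Validate and normalise a residue string
#'
#' Uppercases the input and checks every character against the amino-acid
#' alphabet. Gap characters are never allowed in an input sequence. In strict
#' mode (the default) only the 20 standard one-letter codes pass; lenient
#' mode additionally accepts the extended codes X, B, Z, U, O, J and `*`.
#' Validation is idempotent: `validate_residues(validate_residues(x))` equals
#' `validate_residues(x)`.
#'
#' @param raw Character scalar of residues.
#' @param lenient Accept extended codes?
#' @return The uppercased residue string.
#' @export
validate_residues <- function(raw, lenient = FALSE) {
  if (!is.character(raw) || length(raw) != 1L) {
    mc_input_error("residues must be a single character string")
  }
  res <- toupper(gsub("[ \t\r\n]", "", raw))
  if (!nzchar(res)) mc_input_error("sequence has no residues")
  cc <- chars(res)
  if (any(cc %in% c(GAP_CHAR, "."))) {
    pos <- which(cc %in% c(GAP_CHAR, "."))[1L]
    mc_input_error(sprintf(
      "gap character '%s' at position %d: input sequences must be ungapped",
      cc[pos], pos))
  }
  allowed <- if (lenient) c(STANDARD_AA, EXTENDED_AA) else STANDARD_AA
  bad <- which(!cc %in% allowed)
  if (length(bad)) {
    mc_input_error(sprintf(
      "invalid residue '%s' at position %d (allowed: %s)",
      cc[bad[1L]], bad[1L], paste(allowed, collapse = "")))
  }
  res
}

#' Read protein sequences from FASTA text or a FASTA file
#'
#' @param source Path to a FASTA file, or a character scalar containing FASTA
#'   text itself (recognised when it starts with `>` or contains a newline).
#' @param lenient Accept extended amino-acid codes?
#' @return List of [protein_sequence()] objects, one per record. Residues are
#'   uppercased and internal whitespace/line wrapping is removed.
#' @export
read_fasta <- function(source, lenient = FALSE) {
  if (!is.character(source) || length(source) != 1L) {
    mc_input_error("source must be a single path or FASTA string")
  }
  looks_like_text <- grepl("^[ \t]*>", source) || grepl("\n", source, fixed = TRUE)
  if (!looks_like_text) {
    if (!file.exists(source)) {
      mc_input_error(sprintf("missing sequence file: '%s' does not exist", source))
    }
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- strsplit(source, "\n", fixed = TRUE)[[1L]]
  }
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    mc_input_error("missing sequence: FASTA input contains no records")
  }
  headers <- grepl("^[ \t]*>", lines)
  if (!headers[idx[1L]]) {
    mc_input_error(sprintf(
      "FASTA parse error at line %d: expected a '>' header before sequence data",
      idx[1L]))
  }
  records <- list()
  cur_id <- NULL
  cur_desc <- ""
  cur_seq <- character()
  cur_line <- 0L
  flush <- function() {
    if (is.null(cur_id)) return()
    body <- paste(cur_seq, collapse = "")
    if (!nzchar(gsub("[ \t]", "", body))) {
      mc_input_error(sprintf(
        "FASTA parse error: record '%s' (header at line %d) has no residues",
        cur_id, cur_line))
    }
    records[[length(records) + 1L]] <<- protein_sequence(
      cur_id, body, description = cur_desc, lenient = lenient)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (grepl("^[ \t]*>", ln)) {
      flush()
      hdr <- sub("^[ \t]*>", "", trimws(ln))
      if (!nzchar(hdr)) {
        mc_input_error(sprintf("FASTA parse error at line %d: empty header", i))
      }
      sp <- regexpr("[ \t]", hdr)
      if (sp > 0) {
        cur_id <- substr(hdr, 1L, sp - 1L)
        cur_desc <- trimws(substr(hdr, sp + 1L, nchar(hdr)))
      } else {
        cur_id <- hdr
        cur_desc <- ""
      }
      cur_seq <- character()
      cur_line <- i
    } else {
      cur_seq <- c(cur_seq, ln)
    }
  }
  flush()
  if (!length(records)) {
    mc_input_error("missing sequence: FASTA input contains no records")
  }
  records
}

#' Write protein sequences to a FASTA file
#'
#' Sequence lines are wrapped at 80 characters. Round-trip property:
#' `read_fasta()` of the written file reproduces ids and residues exactly.
#'
#' @param seqs Non-empty list of [protein_sequence()] objects.
#' @param dest Output path.
#' @return `dest`, invisibly.
#' @export
write_fasta <- function(seqs, dest) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  if (!is.list(seqs) || !length(seqs) ||
      !all(vapply(seqs, inherits, logical(1), "protein_sequence"))) {
    mc_input_error("seqs must be a non-empty list of protein_sequence objects")
  }
  out <- unlist(lapply(seqs, function(s) {
    hdr <- if (nzchar(s$description)) paste(s$id, s$description) else s$id
    body <- s$residues
    starts <- seq(1L, nchar(body), by = 80L)
    c(paste0(">", hdr), substring(body, starts, pmin(starts + 79L, nchar(body))))
  }))
  con <- tryCatch(file(dest, "w", encoding = "UTF-8"),
                  error = function(e) mc_input_error(
                    sprintf("cannot write FASTA to '%s': %s", dest, conditionMessage(e))))
  on.exit(close(con))
  writeLines(out, con)
  invisible(dest)
}

# Pick the pattern/subject pair out of parsed FASTA records: the first two
# records are used when one file carries both sequences, with a warning.
#' @noRd
take_pair_record <- function(records, which = c("first", "second")) {
  which <- match.arg(which)
  if (length(records) > 2L) {
    warning(sprintf(
      "FASTA input has %d records; only the first two are used as pattern and subject",
      length(records)), call. = FALSE)
  }
  if (which == "first") records[[1L]] else records[[min(2L, length(records))]]
}
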