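# Search within alignments: indel runs, identity-match regions, subsequence
# occurrences, and single-position lookup. All coordinates are 1-based
# closed alignment-column intervals (the detail view's "PO" field).
#
# Indels are reported per aligned string: role "gap_in_pattern" means the
# gap characters sit in the pattern string (a region present in the subject
# only); "gap_in_subject" is an insertion in the pattern relative to the
# subject.

#' @noRd
maximal_runs <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(r$values)
  data.frame(start = starts[k], end = ends[k], length = r$lengths[k])
}

#' Locate all indels in an alignment
#'
#' @param alignment A `pairwise_alignment`.
#' @return data.frame with columns `role` (`gap_in_pattern` /
#'   `gap_in_subject`), `start` (alignment column) and `length`, holding
#'   every maximal gap run of either aligned string, sorted by start.
#' @export
find_indels <- function(alignment) {
  if (!inherits(alignment, "pairwise_alignment")) {
    mc_input_error("alignment must be a pairwise_alignment")
  }
  empty <- data.frame(role = character(0), start = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (alignment_length(alignment) == 0L) return(empty)
  pc <- chars(alignment$aligned_pattern)
  sc <- chars(alignment$aligned_subject)
  pr <- maximal_runs(pc == GAP_CHAR)
  sr <- maximal_runs(sc == GAP_CHAR)
  out <- rbind(
    if (nrow(pr)) data.frame(role = "gap_in_pattern", start = pr$start,
                             length = pr$length, stringsAsFactors = FALSE),
    if (nrow(sr)) data.frame(role = "gap_in_subject", start = sr$start,
                             length = sr$length, stringsAsFactors = FALSE))
  if (is.null(out) || !nrow(out)) return(empty)
  out <- out[order(out$start, out$role), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate identity-match regions
#'
#' @param alignment A `pairwise_alignment`.
#' @return data.frame with columns `start`, `end`: the maximal runs of
#'   identity columns (both characters residues and equal).
#' @export
find_match_regions <- function(alignment) {
  if (!inherits(alignment, "pairwise_alignment")) {
    mc_input_error("alignment must be a pairwise_alignment")
  }
  if (alignment_length(alignment) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  pc <- chars(alignment$aligned_pattern)
  sc <- chars(alignment$aligned_subject)
  runs <- maximal_runs(pc != GAP_CHAR & sc != GAP_CHAR & pc == sc)
  data.frame(start = runs$start, end = runs$end)
}

#' Find a subsequence within an aligned sequence
#'
#' The query is matched exactly (no mismatches) against the DEGAPPED chosen
#' sequence; hits are mapped back to alignment-column coordinates, so a hit
#' may span gap columns interleaved within it. Overlapping occurrences are
#' all reported.
#'
#' @param alignment A `pairwise_alignment`.
#' @param query Gap-free residue string to search for.
#' @param role Search the `"pattern"` or the `"subject"` string.
#' @return data.frame with columns `start`, `end` (alignment columns).
#' @export
find_subsequence <- function(alignment, query, role = c("pattern", "subject")) {
  role <- match.arg(role)
  if (!inherits(alignment, "pairwise_alignment")) {
    mc_input_error("alignment must be a pairwise_alignment")
  }
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    mc_input_error("query must be a non-empty residue string")
  }
  query <- toupper(query)
  if (grepl(GAP_CHAR, query, fixed = TRUE)) {
    mc_input_error("query must not contain gap characters")
  }
  aligned <- if (role == "pattern") alignment$aligned_pattern else alignment$aligned_subject
  cc <- chars(aligned)
  res_cols <- which(cc != GAP_CHAR)      # alignment column of each residue
  text <- paste(cc[res_cols], collapse = "")
  q <- nchar(query); L <- nchar(text)
  hits <- if (q > L) integer(0) else {
    which(vapply(seq_len(L - q + 1L),
                 function(i) substr(text, i, i + q - 1L) == query,
                 logical(1)))
  }
  data.frame(start = res_cols[hits], end = res_cols[hits + q - 1L])
}

#' Annotated column at a given alignment position
#'
#' @param alignment A `pairwise_alignment`.
#' @param position 1-based alignment column.
#' @param matrix [substitution_matrix()] used for the log-odds annotation.
#' @inheritParams annotate_columns
#' @return One-row data.frame as produced by [annotate_columns()].
#' @export
locate_position <- function(alignment, position, matrix, schemes = NULL,
                            classification = NULL, lenient = FALSE) {
  if (!inherits(alignment, "pairwise_alignment")) {
    mc_input_error("alignment must be a pairwise_alignment")
  }
  L <- alignment_length(alignment)
  if (!is_scalar_number(position) || position != as.integer(position) ||
      position < 1L || position > L) {
    mc_input_error(sprintf(
      "position %s out of range: valid alignment columns are 1..%d",
      as.character(position)[1L], L))
  }
  ann <- annotate_columns(alignment, matrix, schemes = schemes,
                          classification = classification, lenient = lenient)
  ann[as.integer(position), , drop = FALSE]
}
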