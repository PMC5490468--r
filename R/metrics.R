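# Alignment-quality metrics: the four percent-identity variants and the
# per-column annotation (log-odds value, conservation call, identity and
# indel flags, optional classification).
#
# The four PID denominators:
#   PID1 - aligned positions plus INTERNAL gap positions (gap columns whose
#          run does not touch either end of the alignment),
#   PID2 - aligned positions (columns where both characters are residues),
#   PID3 - ungapped length of the shorter INPUT sequence,
#   PID4 - mean ungapped length of the two input sequences.
# PID3/PID4 use the original input lengths carried on the alignment object,
# not the possibly clipped aligned ranges.

#' @noRd
alignment_counts <- function(alignment) {
  L <- alignment_length(alignment)
  if (L == 0L) {
    return(list(L = 0L, identities = 0L, aligned = 0L, gap_cols = 0L,
                internal_gaps = 0L))
  }
  pc <- chars(alignment$aligned_pattern)
  sc <- chars(alignment$aligned_subject)
  gap <- pc == GAP_CHAR | sc == GAP_CHAR
  aligned <- sum(!gap)
  identities <- sum(!gap & pc == sc)
  lead <- if (gap[1L]) rle(gap)$lengths[1L] else 0L
  trail <- if (gap[L]) utils::tail(rle(gap)$lengths, 1L) else 0L
  if (lead == L) trail <- 0L  # fully gapped alignment cannot double-count
  list(L = L, identities = identities, aligned = aligned,
       gap_cols = sum(gap), internal_gaps = sum(gap) - lead - trail)
}

#' Percent identity of an alignment
#'
#' @param alignment A `pairwise_alignment`.
#' @param pid_type Which denominator variant, 1-4 (see Details above).
#' @return Percent value in \[0, 100\]; an empty alignment scores 0.
#' @seealso [pid_set()] for all four at once.
#' @export
percent_identity <- function(alignment, pid_type = 1L) {
  if (!inherits(alignment, "pairwise_alignment")) {
    mc_input_error("alignment must be a pairwise_alignment")
  }
  if (!pid_type %in% 1:4) mc_input_error("pid_type must be 1, 2, 3 or 4")
  cnt <- alignment_counts(alignment)
  denom <- switch(pid_type,
    cnt$aligned + cnt$internal_gaps,
    cnt$aligned,
    min(alignment$pattern_length, alignment$subject_length),
    (alignment$pattern_length + alignment$subject_length) / 2)
  if (denom <= 0) return(0)
  100 * cnt$identities / denom
}

#' All four percent-identity variants
#' @inheritParams percent_identity
#' @return Named numeric vector `c(pid1 = , pid2 = , pid3 = , pid4 = )`.
#' @export
pid_set <- function(alignment) {
  stats::setNames(vapply(1:4, function(k) percent_identity(alignment, k),
                         numeric(1)),
                  paste0("pid", 1:4))
}

#' Annotate an alignment column by column
#'
#' One row per alignment column with the residue pair, the log-odds score of
#' the substitution (NA for residue-gap columns, where it is undefined), the
#' conservation call derived from the score sign, and identity/indel flags.
#' Optionally adds classification columns per scheme for both residues.
#'
#' @param alignment A `pairwise_alignment`.
#' @param matrix The [substitution_matrix()] to score substitutions with.
#' @param schemes Character vector of classification scheme names to append
#'   (as columns `pattern_<scheme>`, `subject_<scheme>`), or `NULL` for none.
#' @param classification Table from [load_classification()]; default bundled.
#' @param lenient Passed to [lookup_score()].
#' @return A data.frame with columns `position`, `pattern_char`,
#'   `subject_char`, `log_odds`, `conservation` (one of conservative /
#'   non_conservative / neutral / undefined), `is_identity`, `is_indel`.
#' @export
annotate_columns <- function(alignment, matrix, schemes = NULL,
                             classification = NULL, lenient = FALSE) {
  if (!inherits(alignment, "pairwise_alignment")) {
    mc_input_error("alignment must be a pairwise_alignment")
  }
  if (!is_substitution_matrix(matrix)) {
    mc_input_error("matrix must be a substitution_matrix")
  }
  L <- alignment_length(alignment)
  if (L == 0L) {
    out <- data.frame(position = integer(0), pattern_char = character(0),
                      subject_char = character(0), log_odds = numeric(0),
                      conservation = character(0), is_identity = logical(0),
                      is_indel = logical(0), stringsAsFactors = FALSE)
    return(out)
  }
  pc <- chars(alignment$aligned_pattern)
  sc <- chars(alignment$aligned_subject)
  is_indel <- pc == GAP_CHAR | sc == GAP_CHAR
  log_odds <- rep(NA_real_, L)
  conservation <- rep("undefined", L)
  for (k in which(!is_indel)) {
    log_odds[k] <- lookup_score(matrix, pc[k], sc[k], lenient = lenient)
    conservation[k] <- if (log_odds[k] > 0) "conservative"
                       else if (log_odds[k] < 0) "non_conservative"
                       else "neutral"
  }
  out <- data.frame(position = seq_len(L), pattern_char = pc, subject_char = sc,
                    log_odds = log_odds, conservation = conservation,
                    is_identity = !is_indel & pc == sc, is_indel = is_indel,
                    stringsAsFactors = FALSE)
  if (!is.null(schemes)) {
    if (is.null(classification)) classification <- classification_default()
    for (sch in schemes) {
      out[[paste0("pattern_", sch)]] <-
        vapply(pc, classify_residue, character(1), scheme = sch,
               table = classification, USE.NAMES = FALSE)
      out[[paste0("subject_", sch)]] <-
        vapply(sc, classify_residue, character(1), scheme = sch,
               table = classification, USE.NAMES = FALSE)
    }
  }
  out
}
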