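# Batch comparison: align one pattern/subject pair under many matrix/penalty
# configurations, compute all metrics and search annotations, rank the
# configurations per key and min-max normalise the values. This is the batch
# counterpart of an interactive overview/detail/search workflow: everything
# a viewer would reveal on demand is precomputed into the report.

RANK_KEYS <- c("score", "pid1", "pid2", "pid3", "pid4")

#' Compare substitution-matrix configurations on one sequence pair
#'
#' Aligns the pair once per configuration and assembles a full comparison
#' report: per-config score, the four percent-identity variants, per-column
#' annotation (with all classification schemes), indels and match regions,
#' plus cross-config rankings and min-max normalised values for the score
#' and each PID type.
#'
#' @param pattern,subject [protein_sequence()] objects or residue strings.
#' @param configs List of [matrix_config()] objects (a single config is
#'   accepted bare); labels must be unique.
#' @param mode Alignment mode, see [align_pair()].
#' @param lenient Accept extended residues / score unknowns as 0.
#' @param allow_identical Identical pattern and subject are a hard error by
#'   default (a diagnostic for accidentally loading one sequence twice); set
#'   `TRUE` to align anyway.
#' @param classification Table from [load_classification()].
#' @return Object of class `comparison_report` with elements `meta`,
#'   `results` (one per config label), `rankings` and `normalized`.
#' @export
run_comparison <- function(pattern, subject, configs,
                           mode = c("global", "local", "overlap",
                                    "global_local", "local_global"),
                           lenient = FALSE, allow_identical = FALSE,
                           classification = NULL) {
  mode <- match.arg(mode)
  if (inherits(configs, "matrix_config")) configs <- list(configs)
  if (!is.list(configs) || !length(configs) ||
      !all(vapply(configs, inherits, logical(1), "matrix_config"))) {
    mc_input_error("configs must be a non-empty list of matrix_config objects")
  }
  labels <- vapply(configs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    mc_input_error(sprintf("duplicate config label '%s': labels must be unique",
                           labels[duplicated(labels)][1L]))
  }
  if (is.character(pattern)) pattern <- protein_sequence("pattern", pattern, lenient = lenient)
  if (is.character(subject)) subject <- protein_sequence("subject", subject, lenient = lenient)
  if (!inherits(pattern, "protein_sequence") || !inherits(subject, "protein_sequence")) {
    mc_input_error("pattern and subject must be protein_sequence objects or strings")
  }
  if (identical(pattern$residues, subject$residues) && !allow_identical) {
    mc_input_error(
      "identical sequences: pattern and subject are the same; pass allow_identical = TRUE to align anyway")
  }
  if (is.null(classification)) classification <- classification_default()
  schemes <- names(classification)

  results <- vector("list", length(configs))
  names(results) <- labels
  for (k in seq_along(configs)) {
    cfg <- configs[[k]]
    aln <- tryCatch(
      align_pair(pattern, subject, cfg, mode = mode, lenient = lenient),
      error = function(e) mc_align_error(
        sprintf("config %s: %s", cfg$label, conditionMessage(e))))
    results[[k]] <- list(
      label = cfg$label,
      matrix = attr(cfg$matrix, "label"),
      gap_open = cfg$gap_open,
      gap_extend = cfg$gap_extend,
      score = aln$score,
      pid = pid_set(aln),
      alignment = aln,
      columns = annotate_columns(aln, cfg$matrix, schemes = schemes,
                                 classification = classification,
                                 lenient = lenient),
      indels = find_indels(aln),
      match_regions = find_match_regions(aln)
    )
  }

  report <- structure(
    list(
      meta = list(
        pattern_id = pattern$id, subject_id = subject$id,
        pattern_length = nchar(pattern$residues),
        subject_length = nchar(subject$residues),
        mode = mode, lenient = lenient,
        n_configs = length(configs),
        tool = "matcompare",
        version = as.character(utils::packageVersion("matcompare")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      ),
      results = results,
      rankings = NULL, normalized = NULL
    ),
    class = "comparison_report"
  )
  report$rankings <- stats::setNames(
    lapply(RANK_KEYS, function(key) rank_configs(report, key)), RANK_KEYS)
  report$normalized <- stats::setNames(
    lapply(RANK_KEYS, function(key) {
      v <- report_values(report, key)
      stats::setNames(normalize_values(v), names(v))
    }), RANK_KEYS)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %s vs %s, %s mode, %d config(s)\n",
              x$meta$pattern_id, x$meta$subject_id, x$meta$mode,
              x$meta$n_configs))
  cat(sprintf("  by score: %s\n", paste(x$rankings$score, collapse = " > ")))
  for (lab in x$rankings$score) {
    r <- x$results[[lab]]
    cat(sprintf("  %-10s %-10s score %9.2f  PID %6.2f / %6.2f / %6.2f / %6.2f\n",
                lab, r$matrix, r$score, r$pid[1L], r$pid[2L], r$pid[3L], r$pid[4L]))
  }
  invisible(x)
}

# Values of one ranking key for every config, named by label.
#' @noRd
report_values <- function(report, key) {
  if (!inherits(report, "comparison_report")) {
    mc_input_error("report must be a comparison_report")
  }
  if (!key %in% RANK_KEYS) {
    mc_input_error(sprintf("unknown ranking key '%s'; available: %s",
                           as.character(key)[1L], paste(RANK_KEYS, collapse = ", ")))
  }
  vapply(report$results, function(r) {
    if (key == "score") r$score else unname(r$pid[key])
  }, numeric(1))
}

#' Rank configurations by a metric
#'
#' @param report A `comparison_report`.
#' @param key One of `"score"`, `"pid1"` .. `"pid4"`.
#' @return Config labels in descending order of the metric; ties broken by
#'   lexicographic label order.
#' @export
rank_configs <- function(report, key = "score") {
  v <- report_values(report, key)
  names(v)[order(-v, names(v), method = "radix")]
}

#' Min-max normalise a set of values
#'
#' Maps the minimum to 0 and the maximum to 1; when all values are equal
#' (including a single value) everything maps to 0.5.
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector in \[0, 1\], same order and names.
#' @export
normalize_values <- function(values) {
  if (!is.numeric(values) || !length(values)) {
    mc_input_error("values must be a non-empty numeric vector")
  }
  rng <- range(values)
  if (rng[1L] == rng[2L]) return(rep(0.5, length(values)))
  (values - rng[1L]) / (rng[2L] - rng[1L])
}

#' Cross-configuration residue histogram at one column
#'
#' Counts the characters (residues and gaps, pattern and subject rows both)
#' appearing at a given alignment column across all configurations'
#' alignments; alignments shorter than the position contribute nothing.
#'
#' @param report A `comparison_report`.
#' @param position 1-based alignment column.
#' @return Named integer vector of counts, sorted by character.
#' @export
column_histogram <- function(report, position) {
  if (!inherits(report, "comparison_report")) {
    mc_input_error("report must be a comparison_report")
  }
  if (!is_scalar_number(position) || position < 1L) {
    mc_input_error("position must be a positive integer")
  }
  position <- as.integer(position)
  obs <- character(0)
  for (r in report$results) {
    aln <- r$alignment
    if (alignment_length(aln) >= position) {
      obs <- c(obs, substr(aln$aligned_pattern, position, position),
               substr(aln$aligned_subject, position, position))
    }
  }
  if (!length(obs)) return(stats::setNames(integer(0), character(0)))
  tab <- table(obs)
  stats::setNames(as.integer(tab), names(tab))
}
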