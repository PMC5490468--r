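# Report serialization: machine-readable JSON (full precision, every
# per-column detail), a compact TSV (one row per config), and a static HTML
# overview with blue -> red bars driven by the min-max normalised values
# (blue = lowest, red = highest).

#' @noRd
range_or_null <- function(rng) {
  if (anyNA(rng)) NULL else as.integer(rng)
}

# Plain-list view of a report matching the documented JSON schema.
#' @noRd
report_to_list <- function(report) {
  configs <- lapply(unname(report$results), function(r) {
    list(
      label = r$label,
      matrix = r$matrix,
      gap_open = r$gap_open,
      gap_extend = r$gap_extend,
      score = r$score,
      pid = list("1" = unname(r$pid[1L]), "2" = unname(r$pid[2L]),
                 "3" = unname(r$pid[3L]), "4" = unname(r$pid[4L])),
      alignment = list(
        pattern = r$alignment$aligned_pattern,
        subject = r$alignment$aligned_subject,
        pattern_range = range_or_null(r$alignment$pattern_range),
        subject_range = range_or_null(r$alignment$subject_range)
      ),
      columns = r$columns,
      indels = r$indels,
      match_regions = r$match_regions
    )
  })
  list(
    meta = report$meta,
    configs = configs,
    rankings = report$rankings,
    normalized = lapply(report$normalized, as.list)
  )
}

#' @noRd
blue_red <- function(v) {
  grDevices::rgb(round(255 * v), 0, round(255 * (1 - v)), maxColorValue = 255)
}

#' @noRd
html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' @noRd
report_to_html <- function(report) {
  keys <- names(report$normalized)
  vals <- lapply(keys, function(k) report_values(report, k))
  names(vals) <- keys
  rows <- vapply(keys, function(k) {
    norm <- report$normalized[[k]]
    order_lab <- report$rankings[[k]]
    cells <- vapply(order_lab, function(lab) {
      sprintf(
        '<td style="background:%s;color:#fff;padding:4px 8px;" title="%s = %.4f">%s<br/><small>%.2f</small></td>',
        blue_red(norm[[lab]]), k, vals[[k]][[lab]], html_escape(lab), vals[[k]][[lab]])
    }, character(1))
    sprintf('<tr class="overview-row" data-key="%s"><th style="text-align:left;padding:4px 8px;">%s</th>%s</tr>',
            k, k, paste(cells, collapse = ""))
  }, character(1))
  detail <- vapply(unname(report$results), function(r) {
    aln <- r$alignment
    paste0(
      sprintf('<h3 id="config-%s">%s &mdash; %s (gap %g, extension %g)</h3>',
              html_escape(r$label), html_escape(r$label), html_escape(r$matrix),
              r$gap_open, r$gap_extend),
      sprintf('<p>score %.4f; PID1 %.2f, PID2 %.2f, PID3 %.2f, PID4 %.2f</p>',
              r$score, r$pid[1L], r$pid[2L], r$pid[3L], r$pid[4L]),
      sprintf('<pre>P: %s\nS: %s</pre>',
              html_escape(aln$aligned_pattern), html_escape(aln$aligned_subject))
    )
  }, character(1))
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>%s vs %s (%s)</title>",
            html_escape(report$meta$pattern_id),
            html_escape(report$meta$subject_id), report$meta$mode),
    "</head><body>",
    sprintf("<h1>Substitution-matrix comparison: %s vs %s</h1>",
            html_escape(report$meta$pattern_id),
            html_escape(report$meta$subject_id)),
    sprintf("<p>mode %s; %d configuration(s); generated %s by %s %s</p>",
            report$meta$mode, report$meta$n_configs, report$meta$timestamp,
            report$meta$tool, report$meta$version),
    "<h2>Overview</h2>",
    "<p>Each row sorts the configurations by one metric; cell colour is the ",
    "min-max normalised value, blue = lowest, red = highest.</p>",
    "<table style=\"border-collapse:collapse;\">",
    paste(rows, collapse = "\n"),
    "</table>",
    "<h2>Details</h2>",
    paste(detail, collapse = "\n"),
    "</body></html>\n"
  )
}

#' Write a comparison report
#'
#' @param report A `comparison_report` from [run_comparison()].
#' @param format `"json"` (full machine-readable report at full precision),
#'   `"tsv"` (one row per config: score and the four PIDs, 2 decimals), or
#'   `"html"` (static overview page with blue-to-red normalised bars and
#'   per-config detail).
#' @param dest Output path.
#' @return `dest`, invisibly.
#' @export
write_report <- function(report, format = c("json", "tsv", "html"), dest) {
  if (!inherits(report, "comparison_report")) {
    mc_input_error("report must be a comparison_report")
  }
  format <- match.arg(format)
  if (!is.character(dest) || length(dest) != 1L || !nzchar(dest)) {
    mc_input_error("dest must be a single path")
  }
  if (format == "json") {
    jsonlite::write_json(report_to_list(report), dest, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else if (format == "tsv") {
    tab <- do.call(rbind, lapply(unname(report$results), function(r) {
      data.frame(label = r$label, matrix = r$matrix,
                 gap_open = r$gap_open, gap_extend = r$gap_extend,
                 score = round(r$score, 2),
                 pid1 = round(unname(r$pid[1L]), 2),
                 pid2 = round(unname(r$pid[2L]), 2),
                 pid3 = round(unname(r$pid[3L]), 2),
                 pid4 = round(unname(r$pid[4L]), 2),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(tab, dest, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(report_to_html(report), dest)
  }
  invisible(dest)
}

#' Re-read a JSON comparison report
#'
#' Convenience parser for round-trip checks and downstream consumers.
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return The parsed report as nested lists/data.frames.
#' @export
read_report_json <- function(path) {
  if (!file.exists(path)) mc_input_error(sprintf("report not found: '%s'", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
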