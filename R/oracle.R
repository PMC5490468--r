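# Exhaustive-enumeration test oracle for the aligner.
#
# Enumerates every admissible alignment of tiny instances as a sequence of
# moves (1 = substitution column, 2 = gap-in-subject column consuming the
# pattern, 3 = gap-in-pattern column consuming the subject), scores each by
# direct column accounting (gap runs charged open + L*extend, terminal runs
# free only for ends-free mode), and returns the maximum. Deliberately
# independent of the Gotoh recurrences in align.R: no cell ever stores a
# partial optimum.

.oracle_cache <- new.env(parent = emptyenv())

# All monotone move paths consuming n pattern and m subject residues
# (no gap/gap columns by construction). Memoised; counts grow like the
# Delannoy numbers, so callers bound n*m.
#' @noRd
move_paths <- function(n, m) {
  key <- sprintf("P%d_%d", n, m)
  hit <- .oracle_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- if (n == 0L && m == 0L) {
    list(integer(0))
  } else {
    out <- list()
    if (n > 0L && m > 0L) {
      out <- c(out, lapply(move_paths(n - 1L, m - 1L), function(p) c(p, 1L)))
    }
    if (n > 0L) out <- c(out, lapply(move_paths(n - 1L, m), function(p) c(p, 2L)))
    if (m > 0L) out <- c(out, lapply(move_paths(n, m - 1L), function(p) c(p, 3L)))
    out
  }
  .oracle_cache[[key]] <- res
  res
}

# Penalty-independent decomposition of every path of a given shape:
# which (pattern, subject) positions sit in substitution columns, plus the
# gap-run counts/lengths both fully charged and with free terminal runs.
#' @noRd
shape_decomp <- function(n, m) {
  key <- sprintf("D%d_%d", n, m)
  hit <- .oracle_cache[[key]]
  if (!is.null(hit)) return(hit)
  paths <- move_paths(n, m)
  np <- length(paths)
  diag_p <- integer(0); diag_s <- integer(0); path_id <- integer(0)
  nruns <- integer(np); totgap <- integer(np)
  nruns_free <- integer(np); totgap_free <- integer(np)
  for (k in seq_len(np)) {
    mv <- paths[[k]]
    i <- cumsum(mv != 3L)   # pattern consumed after each move
    j <- cumsum(mv != 2L)   # subject consumed
    d <- which(mv == 1L)
    diag_p <- c(diag_p, i[d]); diag_s <- c(diag_s, j[d])
    path_id <- c(path_id, rep.int(k, length(d)))
    r <- rle(mv)
    gap_runs <- which(r$values != 1L)
    nruns[k] <- length(gap_runs)
    totgap[k] <- sum(r$lengths[gap_runs])
    drop <- integer(0)
    if (length(gap_runs) && gap_runs[1L] == 1L) drop <- 1L
    last <- length(r$values)
    if (length(gap_runs) && gap_runs[length(gap_runs)] == last &&
        !(last %in% (if (length(drop)) gap_runs[drop] else integer(0)))) {
      drop <- c(drop, length(gap_runs))
    }
    kept <- if (length(drop)) gap_runs[-drop] else gap_runs
    nruns_free[k] <- length(kept)
    totgap_free[k] <- sum(r$lengths[kept])
  }
  res <- list(np = np, diag_p = diag_p, diag_s = diag_s, path_id = path_id,
              nruns = nruns, totgap = totgap,
              nruns_free = nruns_free, totgap_free = totgap_free)
  .oracle_cache[[key]] <- res
  res
}

# Best score over all global alignments of pattern rows a..a+l1-1 against
# subject columns c..c+l2-1 of the substitution table S.
#' @noRd
enum_block_best <- function(S, a, l1, c, l2, open, ext, free_ends = FALSE) {
  d <- shape_decomp(l1, l2)
  sums <- numeric(d$np)
  if (length(d$path_id)) {
    vals <- S[cbind(a - 1L + d$diag_p, c - 1L + d$diag_s)]
    t <- rowsum(vals, d$path_id)
    sums[as.integer(rownames(t))] <- t[, 1L]
  }
  if (free_ends) {
    max(sums + d$nruns_free * open + d$totgap_free * ext)
  } else {
    max(sums + d$nruns * open + d$totgap * ext)
  }
}

#' Exact optimal score by exhaustive enumeration (test oracle)
#'
#' Enumerates every alignment admissible under the mode and scores gap runs
#' with the affine cost, returning the exact optimum. Intended as the
#' independent verification route for [align_pair()]; refuses instances with
#' `length(pattern) * length(subject) > 49`.
#'
#' @inheritParams align_pair
#' @return The optimal score (numeric scalar).
#' @export
enumerate_best_score <- function(pattern, subject, config,
                                 mode = c("global", "local", "overlap",
                                          "global_local", "local_global"),
                                 lenient = FALSE) {
  mode <- match.arg(mode)
  prob <- prepare_alignment_problem(pattern, subject, config, lenient = lenient)
  n <- length(prob$p); m <- length(prob$s)
  if (n * m > 49L) {
    mc_input_error(sprintf(
      "enumeration oracle refuses instances larger than 49 cells (got %d x %d)", n, m))
  }
  S <- prob$S; open <- prob$open; ext <- prob$ext
  if (mode == "global") {
    return(enum_block_best(S, 1L, n, 1L, m, open, ext))
  }
  if (mode == "overlap") {
    return(enum_block_best(S, 1L, n, 1L, m, open, ext, free_ends = TRUE))
  }
  if (mode == "global_local") {
    best <- open + n * ext  # whole pattern against the empty subject substring
    for (l2 in 1:m) {
      for (c in 1:(m - l2 + 1L)) {
        best <- max(best, enum_block_best(S, 1L, n, c, l2, open, ext))
      }
    }
    return(best)
  }
  if (mode == "local_global") {
    best <- open + m * ext
    for (l1 in 1:n) {
      for (a in 1:(n - l1 + 1L)) {
        best <- max(best, enum_block_best(S, a, l1, 1L, m, open, ext))
      }
    }
    return(best)
  }
  # local: best global alignment over every non-empty substring pair,
  # floored at the empty alignment's score of 0
  best <- 0
  for (l1 in 1:n) {
    for (a in 1:(n - l1 + 1L)) {
      for (l2 in 1:m) {
        for (c in 1:(m - l2 + 1L)) {
          best <- max(best, enum_block_best(S, a, l1, c, l2, open, ext))
        }
      }
    }
  }
  best
}
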