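six_configs <- function() {
  # two matrices under three penalty sets each, master-file style labels
  b62 <- load_predefined("BLOSUM62")
  p250 <- load_predefined("PAM250")
  pens <- list(c(-3.2, -0.1), c(-10, -0.6), c(-7.5, -0.9))
  c(lapply(0:2, function(k) matrix_config(p250, pens[[k + 1L]][1L],
                                          pens[[k + 1L]][2L],
                                          label = paste0("CM", k))),
    lapply(3:5, function(k) matrix_config(b62, pens[[k - 2L]][1L],
                                          pens[[k - 2L]][2L],
                                          label = paste0("CM", k))))
}

demo_pair <- function() {
  p <- random_sequence(fixture_spec(seed = 41L, lengths = c(60L, 60L)), id = "demoP")
  s <- mutate_sequence(p, fixture_spec(seed = 42L, mutation_rate = 0.25,
                                       indel_rate = 0.05))
  list(p = p, s = s)
}

test_that("run_comparison produces one result block per config plus rankings", {
  pair <- demo_pair()
  rep6 <- run_comparison(pair$p, pair$s, six_configs(), mode = "local")
  expect_s3_class(rep6, "comparison_report")
  expect_equal(names(rep6$results), paste0("CM", 0:5))
  expect_length(rep6$rankings, 5L)
  for (key in names(rep6$rankings)) {
    expect_setequal(rep6$rankings[[key]], paste0("CM", 0:5))  # permutation
    norm <- rep6$normalized[[key]]
    expect_true(all(norm >= 0 & norm <= 1))
    vals <- vapply(rep6$results, function(r) {
      if (key == "score") r$score else unname(r$pid[key])
    }, numeric(1))
    if (max(vals) > min(vals)) {
      expect_equal(unname(norm[which.max(vals)]), 1)
      expect_equal(unname(norm[which.min(vals)]), 0)
    }
  }
})

test_that("rankings agree with an independent sort oracle", {
  pair <- demo_pair()
  rep6 <- run_comparison(pair$p, pair$s, six_configs(), mode = "global")
  for (key in c("score", "pid1", "pid2", "pid3", "pid4")) {
    vals <- vapply(rep6$results, function(r) {
      if (key == "score") r$score else unname(r$pid[key])
    }, numeric(1))
    # independent sort, with the documented lexicographic tie-break
    oracle <- names(vals)[order(-vals, names(vals))]
    expect_equal(rank_configs(rep6, key), oracle)
  }
  expect_error(rank_configs(rep6, "pid9"), "unknown ranking key",
               class = "mc_input_error")
})

test_that("degenerate and duplicate configurations behave as documented", {
  pair <- demo_pair()
  one <- run_comparison(pair$p, pair$s,
                        list(matrix_config(load_predefined("BLOSUM62"),
                                           -10, -0.5, label = "only")),
                        mode = "global")
  expect_equal(one$rankings$score, "only")
  expect_equal(unname(one$normalized$score), 0.5)

  # equal matrix and penalties under two labels -> identical numbers
  cfgs <- list(matrix_config(load_predefined("PAM70"), -10, -0.5, label = "A"),
               matrix_config(load_predefined("PAM70"), -10, -0.5, label = "B"))
  both <- run_comparison(pair$p, pair$s, cfgs, mode = "overlap")
  expect_equal(both$results$A$score, both$results$B$score)
  expect_equal(both$results$A$pid, both$results$B$pid)
  expect_equal(both$rankings$score, c("A", "B"))  # tie broken by label

  dup <- list(matrix_config(load_predefined("PAM70"), -10, -0.5, label = "A"),
              matrix_config(load_predefined("PAM70"), -5, -0.5, label = "A"))
  expect_error(run_comparison(pair$p, pair$s, dup), "duplicate config label",
               class = "mc_input_error")
  expect_error(run_comparison(pair$p, pair$p, cfgs), "identical sequences",
               class = "mc_input_error")
  ok <- run_comparison(pair$p, pair$p, cfgs, allow_identical = TRUE)
  expect_equal(unname(ok$results$A$pid), rep(100, 4))
})

test_that("normalize_values maps min to 0, max to 1, order-preserving", {
  expect_equal(normalize_values(c(64, 68, 72)), c(0, 0.5, 1))
  expect_equal(normalize_values(7), 0.5)
  expect_equal(normalize_values(c(3, 3, 3)), c(0.5, 0.5, 0.5))
  expect_error(normalize_values(numeric(0)), class = "mc_input_error")
  for (k in 1:20) {
    v <- with_test_seed(k, stats::rnorm(sample(2:9, 1)))
    nv <- normalize_values(v)
    expect_equal(min(nv), 0); expect_equal(max(nv), 1)
    expect_equal(order(nv), order(v))
  }
})

test_that("column_histogram counts characters across configs", {
  one <- run_comparison("EAC", "QAC",
                        matrix_config(load_predefined("BLOSUM62"), -10, -0.5,
                                      label = "B62"),
                        mode = "global")
  expect_equal(column_histogram(one, 1L), c(E = 1L, Q = 1L))

  pair <- demo_pair()
  rep6 <- run_comparison(pair$p, pair$s, six_configs(), mode = "global")
  lens <- vapply(rep6$results, function(r) nchar(r$alignment$aligned_pattern),
                 integer(1))
  for (pos in c(1L, min(lens), max(lens))) {
    h <- column_histogram(rep6, pos)
    expect_equal(sum(h), 2L * sum(lens >= pos))
  }
  # identical configs double the single-config counts
  cfgs <- list(matrix_config(load_predefined("PAM70"), -10, -0.5, label = "A"),
               matrix_config(load_predefined("PAM70"), -10, -0.5, label = "B"))
  both <- run_comparison(pair$p, pair$s, cfgs, mode = "global")
  solo <- run_comparison(pair$p, pair$s, cfgs[1L], mode = "global")
  h2 <- column_histogram(both, 5L); h1 <- column_histogram(solo, 5L)
  expect_equal(h2, h1 * 2L)
})

test_that("JSON report round-trips and is deterministic up to timestamp", {
  pair <- demo_pair()
  rep2 <- run_comparison(pair$p, pair$s, six_configs()[c(1, 4)], mode = "local")
  dest <- withr::local_tempfile(fileext = ".json")
  write_report(rep2, "json", dest)
  back <- read_report_json(dest)
  expect_equal(back$meta$pattern_id, "demoP")
  expect_length(back$configs$label, 2L)
  for (k in seq_along(back$configs$label)) {
    lab <- back$configs$label[k]
    r <- rep2$results[[lab]]
    expect_equal(back$configs$score[k], r$score)
    expect_equal(unname(unlist(back$configs$pid[k, ])), unname(r$pid))
    expect_equal(back$configs$alignment$pattern[k], r$alignment$aligned_pattern)
    # PIDs re-derivable from the serialized alignment strings
    rebuilt <- new_alignment(back$configs$alignment$pattern[k],
                             back$configs$alignment$subject[k],
                             mode = "local",
                             pattern_length = back$meta$pattern_length,
                             subject_length = back$meta$subject_length)
    expect_equal(unname(pid_set(rebuilt)), unname(r$pid))
  }
  expect_setequal(names(back$rankings), c("score", paste0("pid", 1:4)))

  # determinism: identical inputs -> byte-identical JSON minus the timestamp
  rep2b <- run_comparison(pair$p, pair$s, six_configs()[c(1, 4)], mode = "local")
  dest2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep2b, "json", dest2)
  strip_ts <- function(f) grep("timestamp", readLines(f), invert = TRUE, value = TRUE)
  expect_identical(strip_ts(dest), strip_ts(dest2))
})

test_that("TSV and HTML reports have the documented structure", {
  pair <- demo_pair()
  rep6 <- run_comparison(pair$p, pair$s, six_configs(), mode = "global")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep6, "tsv", tsv)
  lines <- readLines(tsv)
  expect_length(lines, 1L + 6L)  # header + one row per config
  expect_equal(strsplit(lines[1L], "\t")[[1L]],
               c("label", "matrix", "gap_open", "gap_extend", "score",
                 paste0("pid", 1:4)))
  html <- withr::local_tempfile(fileext = ".html")
  write_report(rep6, "html", html)
  page <- paste(readLines(html), collapse = "\n")
  for (key in c("score", paste0("pid", 1:4))) {
    expect_match(page, sprintf('class="overview-row" data-key="%s"', key))
  }
  expect_error(write_report(rep6, "xml", tsv))
})

test_that("the CLI runs end to end with documented exit codes", {
  dir <- withr::local_tempdir()
  pair <- demo_pair()
  pfa <- file.path(dir, "p.fa"); sfa <- file.path(dir, "s.fa")
  write_fasta(pair$p, pfa); write_fasta(pair$s, sfa)
  writeLines("A C\nA 1 -1\nC -1 1", file.path(dir, "toy.txt"))
  master <- file.path(dir, "master.txt")
  writeLines(c("toy.txt -3.2 -0.1", "toy.txt -10 -0.6"), master)
  out <- file.path(dir, "report.json"); tsv <- file.path(dir, "report.tsv")

  code <- suppressMessages(run_cli(c(
    "--pattern", pfa, "--subject", sfa,
    "--predefined", "BLOSUM62:-10:-0.5,PAM70:-7:-1",
    "--mode", "global-local", "--out", out, "--tsv", tsv,
    "--log-level", "quiet")))
  expect_equal(code, 0L)
  back <- read_report_json(out)
  expect_setequal(back$configs$label, c("BLOSUM62", "PAM70"))
  expect_equal(back$meta$mode, "global_local")
  expect_length(readLines(tsv), 3L)

  # custom master file -> CM labels; both sequences from one two-record file
  pair_fa <- file.path(dir, "pair.fa")
  write_fasta(list(pair$p, pair$s), pair_fa)
  code <- suppressMessages(run_cli(c(
    "--pattern", pair_fa, "--custom", master,
    "--mode", "local", "--out", out, "--log-level", "quiet", "--lenient")))
  expect_equal(code, 0L)
  expect_equal(read_report_json(out)$configs$label, c("CM0", "CM1"))

  # input errors -> exit 2
  expect_equal(suppressMessages(run_cli(c("--out", out))), 2L)
  expect_equal(suppressMessages(run_cli(c(
    "--pattern-seq", "MKV", "--subject-seq", "MKL",
    "--mode", "sideways", "--predefined", "BLOSUM62:-10:-1",
    "--out", out))), 2L)
  expect_equal(suppressMessages(run_cli(c(
    "--pattern-seq", "MKV", "--subject-seq", "MKV",
    "--predefined", "BLOSUM62:-10:-1", "--mode", "global",
    "--out", out))), 2L)  # identical sequences
  # alignment failure -> exit 3 (residue outside custom matrix alphabet)
  expect_equal(suppressMessages(run_cli(c(
    "--pattern-seq", "MKV", "--subject-seq", "MKL",
    "--custom", master, "--mode", "global", "--out", out))), 3L)
})
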