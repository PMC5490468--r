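MODES <- c("global", "local", "overlap", "global_local", "local_global")

test_that("identity alignment sums diagonal entries, no gaps", {
  b62 <- load_predefined("BLOSUM62")
  cfg <- matrix_config(b62, -10, -0.5, label = "B62")
  res <- "MKVLAW"
  a <- align_pair(res, paste0(res, ""), cfg, mode = "global")
  expected <- sum(vapply(strsplit(res, "")[[1L]],
                         function(r) lookup_score(b62, r, r), numeric(1)))
  expect_equal(a$score, expected)
  expect_equal(a$aligned_pattern, res)
  expect_equal(a$aligned_subject, res)
  expect_equal(a$pattern_range, c(1L, 6L))
})

test_that("worked global example: AA vs A under toy scoring", {
  # one match (+1) plus one length-1 gap (-2 - 1) = -2
  cfg <- toy_config(gap_open = -2, gap_extend = -1)
  a <- align_pair("AA", "A", cfg, mode = "global")
  expect_equal(a$score, -2)
  expect_equal(enumerate_best_score("AA", "A", cfg, mode = "global"), -2)
  expect_equal(nchar(a$aligned_pattern), 2L)
  expect_equal(sort(strsplit(a$aligned_subject, "")[[1L]]), c("-", "A"))
})

test_that("local alignment floors at zero with empty-range result", {
  # all-negative scoring: no positive-scoring pair exists
  m <- parse_matrix_text("A C\nA -1 -2\nC -2 -1", label = "neg")
  cfg <- matrix_config(m, -5, -1, label = "neg")
  a <- align_pair("AAA", "CCC", cfg, mode = "local")
  expect_equal(a$score, 0)
  expect_equal(nchar(a$aligned_pattern), 0L)
  expect_true(all(is.na(a$pattern_range)))
  expect_equal(enumerate_best_score("AAA", "CCC", cfg, mode = "local"), 0)
})

test_that("mixed modes span the full named sequence", {
  cfg <- toy_config()
  p <- "ACDE"; s <- "GGACDEGG"
  gl <- align_pair(p, s, cfg, mode = "global_local")
  expect_equal(gsub("-", "", gl$aligned_pattern), p)   # whole pattern
  expect_equal(gl$pattern_range, c(1L, 4L))
  expect_equal(gl$subject_range, c(3L, 6L))
  expect_equal(gl$score, 4)
  lg <- align_pair(s, p, cfg, mode = "local_global")   # whole subject
  expect_equal(gsub("-", "", lg$aligned_subject), p)
  expect_equal(lg$score, 4)
})

test_that("overlap mode gives free terminal gaps", {
  cfg <- toy_config(gap_open = -5, gap_extend = -2)
  a <- align_pair("AACC", "CCGG", cfg, mode = "overlap")
  expect_equal(a$score, 2)  # overlap CC/CC; terminal gaps free
  expect_equal(gsub("-", "", a$aligned_pattern), "AACC")
  expect_equal(gsub("-", "", a$aligned_subject), "CCGG")
  expect_equal(rescore_alignment(a, cfg), a$score)
})

test_that("oracle equivalence on random small instances, every mode", {
  for (k in 1:60) {
    prob <- random_problem(k)
    for (md in MODES) {
      a <- align_pair(prob$pattern, prob$subject, prob$config, mode = md)
      e <- enumerate_best_score(prob$pattern, prob$subject, prob$config, mode = md)
      expect_equal(a$score, e,
                   label = sprintf("mode %s seed %d dp score", md, k),
                   expected.label = "enumeration optimum")
      # reconstruction: column-wise rescoring reproduces the score
      expect_equal(rescore_alignment(a, prob$config), a$score,
                   label = sprintf("mode %s seed %d rescore", md, k))
    }
  }
})

test_that("scores agree with the reference aligner on random instances", {
  # third, fully external route (Biostrings), all five modes
  bt_types <- c(global = "global", local = "local", overlap = "overlap",
                global_local = "global-local", local_global = "local-global")
  for (k in 1:25) {
    prob <- random_problem(k + 500L, lengths = c(2L, 10L))
    bmat <- unclass(prob$config$matrix)
    storage.mode(bmat) <- "double"
    for (md in MODES) {
      a <- align_pair(prob$pattern, prob$subject, prob$config, mode = md)
      b <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(prob$pattern$residues),
        Biostrings::AAString(prob$subject$residues),
        substitutionMatrix = bmat,
        gapOpening = -prob$config$gap_open,
        gapExtension = -prob$config$gap_extend,
        type = bt_types[[md]], scoreOnly = TRUE)
      expect_equal(a$score, b, tolerance = 1e-6,
                   label = sprintf("mode %s seed %d", md, k))
    }
  }
})

test_that("alignment invariants hold on random instances", {
  for (k in 1:40) {
    prob <- random_problem(k + 100L)
    cfg <- prob$config
    for (md in MODES) {
      a <- align_pair(prob$pattern, prob$subject, cfg, mode = md)
      expect_equal(nchar(a$aligned_pattern), nchar(a$aligned_subject))
      pc <- strsplit(a$aligned_pattern, "")[[1L]]
      sc <- strsplit(a$aligned_subject, "")[[1L]]
      expect_false(any(pc == "-" & sc == "-"))
      # removing gaps reproduces the residues inside the reported range
      if (!anyNA(a$pattern_range)) {
        expect_equal(gsub("-", "", a$aligned_pattern),
                     substr(prob$pattern$residues, a$pattern_range[1L],
                            a$pattern_range[2L]))
      }
      if (!anyNA(a$subject_range)) {
        expect_equal(gsub("-", "", a$aligned_subject),
                     substr(prob$subject$residues, a$subject_range[1L],
                            a$subject_range[2L]))
      }
    }
    # score symmetry for symmetric matrices
    g1 <- align_pair(prob$pattern, prob$subject, cfg, mode = "global")$score
    g2 <- align_pair(prob$subject, prob$pattern, cfg, mode = "global")$score
    expect_equal(g1, g2)
    gl <- align_pair(prob$pattern, prob$subject, cfg, mode = "global_local")$score
    lg <- align_pair(prob$subject, prob$pattern, cfg, mode = "local_global")$score
    expect_equal(gl, lg)
    # local optimum at least the best single-pair substitution and >= 0
    loc <- align_pair(prob$pattern, prob$subject, cfg, mode = "local")$score
    best_pair <- max(outer(strsplit(prob$pattern$residues, "")[[1L]],
                           strsplit(prob$subject$residues, "")[[1L]],
                           Vectorize(function(a, b) lookup_score(cfg$matrix, a, b))))
    expect_gte(loc, max(0, best_pair))
  }
})

test_that("more negative gap penalties never increase the score", {
  for (k in 1:12) {
    prob <- random_problem(k + 200L, lengths = c(3L, 6L))
    cfg <- prob$config
    worse_open <- matrix_config(cfg$matrix, cfg$gap_open - 2, cfg$gap_extend,
                                label = "wo")
    worse_ext <- matrix_config(cfg$matrix, cfg$gap_open, cfg$gap_extend - 1,
                               label = "we")
    for (md in MODES) {
      base <- align_pair(prob$pattern, prob$subject, cfg, mode = md)$score
      expect_lte(align_pair(prob$pattern, prob$subject, worse_open, mode = md)$score,
                 base + 1e-9)
      expect_lte(align_pair(prob$pattern, prob$subject, worse_ext, mode = md)$score,
                 base + 1e-9)
    }
  }
})

test_that("alignment errors are tailored", {
  cfg <- toy_config()
  expect_error(align_pair("", "A", cfg), class = "mc_input_error")
  # residue outside matrix alphabet in strict mode
  expect_error(align_pair("AW", "AC", cfg, mode = "global"),
               "poorly constructed", class = "mc_align_error")
  # lenient mode scores the unknown residue 0
  a <- align_pair("AW", "AC", cfg, mode = "global", lenient = TRUE)
  expect_equal(a$score, 1)  # A:A = 1, W:C = 0
  # oracle refuses big instances
  big <- paste(rep("A", 20), collapse = "")
  expect_error(enumerate_best_score(big, big, cfg), "refuses",
               class = "mc_input_error")
})
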