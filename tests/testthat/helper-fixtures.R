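# Shared fixtures, all generated in code (nothing checked in).

TOY_ALPHABET <- c("A", "C", "D", "E", "G")

# match +1 / mismatch -1 over a small alphabet
toy_matrix <- function(alphabet = TOY_ALPHABET) {
  n <- length(alphabet)
  m <- matrix(-1, n, n, dimnames = list(alphabet, alphabet))
  diag(m) <- 1
  substitution_matrix(m, label = "toy")
}

toy_config <- function(gap_open = -2, gap_extend = -1, ...) {
  matrix_config(toy_matrix(...), gap_open, gap_extend, label = "toy")
}

# one random small alignment problem: sequences, matrix, penalties
random_problem <- function(seed, lengths = c(1L, 6L), alphabet = TOY_ALPHABET,
                           value_range = c(-5L, 5L)) {
  p <- random_sequence(fixture_spec(seed = seed * 3L + 1L, lengths = lengths,
                                    alphabet = alphabet), id = "p")
  s <- random_sequence(fixture_spec(seed = seed * 3L + 2L, lengths = lengths,
                                    alphabet = alphabet), id = "s")
  mat <- random_matrix(fixture_spec(seed = seed * 3L + 3L, alphabet = alphabet,
                                    matrix_value_range = value_range))
  pen <- with_test_seed(seed * 3L + 4L, -round(stats::runif(2, 0, c(10, 3)), 1))
  list(pattern = p, subject = s,
       config = matrix_config(mat, pen[1L], pen[2L], label = paste0("rp", seed)))
}

# protein-scale random alignment under a bundled matrix and random mode
random_alignment_case <- function(seed, lengths = c(5L, 25L),
                                  modes = c("global", "local", "overlap",
                                            "global_local", "local_global")) {
  p <- random_sequence(fixture_spec(seed = seed * 7L + 1L, lengths = lengths))
  s <- mutate_sequence(p, fixture_spec(seed = seed * 7L + 2L,
                                       mutation_rate = 0.3, indel_rate = 0.1))
  cfg <- matrix_config(load_predefined("BLOSUM62"), -10, -0.5, label = "B62")
  mode <- modes[(seed %% length(modes)) + 1L]
  list(alignment = align_pair(p, s, cfg, mode = mode), config = cfg,
       pattern = p, subject = s)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
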