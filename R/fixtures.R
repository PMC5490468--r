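# Deterministic synthetic-input generator: random protein sequences,
# mutated partners, and random valid substitution matrices. A single integer
# seed drives R's default RNG stream; the caller's RNG state is saved and
# restored, so fixture generation never perturbs other randomness. Not a
# biological evolution simulator - just reproducible, contract-valid inputs.

#' Specification for synthetic fixtures
#'
#' Defaults describe a generic protein-scale test world: sequence lengths
#' 30-80 residues over the 20 standard amino acids, 10% substitution and 2%
#' indel rate for mutated partners, and matrix values spanning the BLOSUM62
#' integer range (-4..11).
#'
#' @param seed Integer seed; the sole source of randomness.
#' @param lengths Length-2 integer range for sequence lengths.
#' @param alphabet Residue subset to draw from.
#' @param mutation_rate Per-position substitution probability in \[0, 1\].
#' @param indel_rate Per-position insertion/deletion probability in \[0, 1\].
#' @param matrix_value_range Length-2 integer interval for off-diagonal
#'   matrix values; the upper bound must be >= 1 so diagonals can be positive.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, lengths = c(30L, 80L),
                         alphabet = STANDARD_AA,
                         mutation_rate = 0.1, indel_rate = 0.02,
                         matrix_value_range = c(-4L, 11L)) {
  if (!is_scalar_number(seed)) mc_input_error("seed must be a single integer")
  if (length(lengths) != 2L || any(lengths < 1L) || lengths[1L] > lengths[2L]) {
    mc_input_error("lengths must be an increasing range of positive integers")
  }
  if (!length(alphabet)) mc_input_error("alphabet must be non-empty")
  for (r in list(mutation_rate, indel_rate)) {
    if (!is_scalar_number(r) || r < 0 || r > 1) {
      mc_input_error("rates must lie in [0, 1]")
    }
  }
  if (length(matrix_value_range) != 2L ||
      matrix_value_range[1L] > matrix_value_range[2L] ||
      matrix_value_range[2L] < 1L) {
    mc_input_error("matrix_value_range must be an interval with upper bound >= 1")
  }
  structure(
    list(seed = as.integer(seed), lengths = as.integer(lengths),
         alphabet = toupper(alphabet), mutation_rate = mutation_rate,
         indel_rate = indel_rate,
         matrix_value_range = as.integer(matrix_value_range)),
    class = "fixture_spec"
  )
}

#' Generate a random protein sequence
#' @param spec A [fixture_spec()].
#' @param id Identifier for the sequence.
#' @return A [protein_sequence()], fully reproducible from `spec$seed`.
#' @export
random_sequence <- function(spec, id = "random") {
  if (!inherits(spec, "fixture_spec")) mc_input_error("spec must be a fixture_spec")
  with_seed(spec$seed, {
    len <- if (spec$lengths[1L] == spec$lengths[2L]) spec$lengths[1L] else
      sample(spec$lengths[1L]:spec$lengths[2L], 1L)
    res <- paste(sample(spec$alphabet, len, replace = TRUE), collapse = "")
    protein_sequence(id, res, lenient = TRUE)
  })
}

#' Derive a mutated partner sequence
#'
#' Applies per-position substitutions (always to a DIFFERENT residue) at
#' `mutation_rate` and insertions/deletions at `indel_rate`. With both rates
#' zero the input is returned unchanged (up to the id suffix).
#'
#' @param seq A [protein_sequence()] to mutate.
#' @param spec A [fixture_spec()]; its seed makes the mutant reproducible.
#' @return A [protein_sequence()] with id `<seq$id>_mut`.
#' @export
mutate_sequence <- function(seq, spec) {
  if (!inherits(seq, "protein_sequence")) mc_input_error("seq must be a protein_sequence")
  if (!inherits(spec, "fixture_spec")) mc_input_error("spec must be a fixture_spec")
  with_seed(spec$seed + 1L, {
    cc <- chars(seq$residues)
    # substitutions
    hit <- stats::runif(length(cc)) < spec$mutation_rate
    for (k in which(hit)) {
      alt <- setdiff(spec$alphabet, cc[k])
      if (length(alt)) cc[k] <- if (length(alt) == 1L) alt else sample(alt, 1L)
    }
    # indels: per position, an independent chance of deleting it or of
    # inserting one random residue after it
    if (spec$indel_rate > 0) {
      del <- stats::runif(length(cc)) < spec$indel_rate
      ins <- stats::runif(length(cc)) < spec$indel_rate
      out <- character(0)
      for (k in seq_along(cc)) {
        if (!del[k]) out <- c(out, cc[k])
        if (ins[k]) {
          out <- c(out, if (length(spec$alphabet) == 1L) spec$alphabet
                        else sample(spec$alphabet, 1L))
        }
      }
      if (!length(out)) out <- cc[1L]  # never return an empty sequence
      cc <- out
    }
    protein_sequence(paste0(seq$id, "_mut"), paste(cc, collapse = ""),
                     lenient = TRUE)
  })
}

#' Generate a random valid substitution matrix
#'
#' Symmetric, integer-valued within `matrix_value_range`, with a strictly
#' positive diagonal; always passes [substitution_matrix()] validation.
#'
#' @param spec A [fixture_spec()].
#' @param label Matrix label.
#' @return A [substitution_matrix()] over `spec$alphabet`.
#' @export
random_matrix <- function(spec, label = "random") {
  if (!inherits(spec, "fixture_spec")) mc_input_error("spec must be a fixture_spec")
  with_seed(spec$seed + 2L, {
    ab <- spec$alphabet
    n <- length(ab)
    lo <- spec$matrix_value_range[1L]; hi <- spec$matrix_value_range[2L]
    vals <- matrix(0L, n, n, dimnames = list(ab, ab))
    for (i in seq_len(n)) {
      for (j in i:n) {
        v <- if (i == j) {
          dlo <- max(1L, lo)
          if (dlo == hi) hi else sample(dlo:hi, 1L)
        } else {
          if (lo == hi) lo else sample(lo:hi, 1L)
        }
        vals[i, j] <- v; vals[j, i] <- v
      }
    }
    substitution_matrix(vals, label = label)
  })
}
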