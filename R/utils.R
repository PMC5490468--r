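# Internal helpers shared across modules.

GAP_CHAR <- "-"
STANDARD_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
EXTENDED_AA <- c("B", "J", "Z", "X", "U", "O", "*")

#' @noRd
mc_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "mc_error")))
}

mc_input_error <- function(msg) mc_error(msg, "mc_input_error")
mc_align_error <- function(msg) mc_error(msg, "mc_align_error")

#' @noRd
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' @noRd
degap <- function(x) gsub(GAP_CHAR, "", x, fixed = TRUE)

# Run a block under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
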