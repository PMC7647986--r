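#' Derive a per-unit random seed from a master seed
#'
#' Counter-based derivation so that per-subject (or per-replicate) random
#' streams do not depend on the order in which units are generated. The
#' result is always a valid 32-bit integer seed.
#'
#' @param master Integer master seed.
#' @param idx Integer counter (subject index, replicate index, ...).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, idx) {
  master <- as.numeric(master)
  idx <- as.numeric(idx)
  x <- (abs(master) %% 1000003) * 2017 + abs(idx) * 7919 + 1
  as.integer(x %% 2147483647)
}

# Run code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_hinge <- function(...) stop(..., call. = FALSE)

# unordered-pair key for integer pairs (1-based, i <= j)
pair_key <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  (lo - 1) * n + hi
}
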