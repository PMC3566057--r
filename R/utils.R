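## Internal helpers shared across modules.

#' Derive a child seed from a master seed and a string key
#'
#' Stochastic stages of the pipeline each receive their own seed derived
#' deterministically from one master seed and a stable label (e.g. the
#' species name), so that per-species results do not depend on the order in
#' which species are processed.
#'
#' @param master_seed single integer master seed.
#' @param key character label identifying the consumer of the seed.
#' @return a single integer in \code{[0, 2^31 - 105)}.
#' @export
derive_seed <- function(master_seed, key) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed),
            length(key) == 1L, is.character(key))
  m <- 2147483543            # large prime-ish modulus < 2^31, doubles stay exact
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% m
  as.integer(((abs(master_seed) %% m) * 69069 + h) %% m)
}

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

## stop() with a consistent prefix, no call in the condition
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
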