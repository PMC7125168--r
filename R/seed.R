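#' Derive a reproducible per-stage seed from a top-level seed
#'
#' All randomness in the package flows from one top-level integer seed.
#' Each stochastic stage (data generation, fold assignment, forest fitting,
#' permutation draws, ...) derives its own seed from the top-level seed plus
#' a string tag naming the stage, so stages are independently reproducible
#' and no stage consumes another stage's stream.
#'
#' The derivation is a plain polynomial rolling hash of the concatenated
#' tokens, reduced modulo 2^31 - 1 so the result is always a valid R
#' integer seed.
#'
#' @param seed integer top-level seed.
#' @param ... further tokens (band names, stage tags, replicate numbers)
#'   coerced to character and hashed together with `seed`.
#' @return An integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "Alpha", "edges")
#' @export
derive_seed <- function(seed, ...) {
  tokens <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                  collapse = "/")
  h <- 0
  for (b in utf8ToInt(tokens)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
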