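#' Derive a child seed from a master seed
#'
#' Stochastic stages (simulation, each MCMC chain, each replicate of a
#' simulation study) are seeded independently so that any stage can be rerun
#' in isolation.  Child seeds are produced from a single master seed by a
#' counter-based multiplicative congruential scheme over the Mersenne prime
#' 2^31 - 1, so every derived seed is a valid 32-bit integer seed.
#'
#' @param seed Master seed (single integer).
#' @param stage Character tag of the pipeline stage (e.g. `"simulate"`).
#' @param index Replicate or chain counter within the stage.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "simulate", 1)
#' derive_seed(1, "chain", 3)
derive_seed <- function(seed, stage = "stage", index = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  m <- 2147483647           # 2^31 - 1, Mersenne prime
  h <- (as.numeric(seed) %% m + 1)
  # fold the stage tag in, character by character
  for (code in utf8ToInt(stage)) {
    h <- (h * 69621 + code) %% m
  }
  h <- (h * 69621 + as.numeric(index)) %% m
  as.integer(h + (h == 0))
}
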