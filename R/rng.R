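#' Derive a named random-number substream seed
#'
#' All stochastic stages of the pipeline draw their seed from a single master
#' seed combined with a stage label, so that adding or reordering stages does
#' not shift the random numbers consumed by the others.
#'
#' @param seed Master seed (single number).
#' @param stage Character label of the stage, e.g. `"step2"`.
#' @return An integer seed suitable for [set.seed()].
#' @export
#' @examples
#' stage_seed(42, "step1") != stage_seed(42, "step2")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L)
  # 31-ary rolling hash over the stage label, kept below 2^31 so the result
  # is a valid R integer on every platform
  m <- 2147483587
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% m
  as.integer((abs(seed) %% m + h) %% m)
}
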