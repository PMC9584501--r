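#' Derive a stage-specific RNG seed from a master seed
#'
#' All randomness in the package flows from one top-level seed. Each pipeline
#' stage (weight initialization, fold assignment, augmentation noise, batch
#' shuffling, ...) draws from its own substream so that, e.g., changing the
#' augmentation settings does not perturb weight initialization.
#'
#' @param seed master integer seed.
#' @param stream stage name, e.g. `"init"`, `"folds"`, `"noise"`, `"shuffle"`.
#' @param index optional integer sub-index (fold number, epoch number, ...).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # cheap string hash (djb2) folded with the master seed and sub-index
  h <- 5381
  for (ch in utf8ToInt(stream)) h <- (h * 33 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)
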