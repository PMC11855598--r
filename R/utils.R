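# internal helpers shared across modules

geomean <- function(x) {
  if (length(x) == 0L) stop("empty vector: geometric mean undefined")
  if (any(x <= 0)) stop("non-positive values: geometric mean undefined")
  exp(mean(log(x)))
}

# round half away from zero, like the printed tables (R's round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  }
  invisible(x)
}

#' Derive deterministic sub-seeds from a master seed
#'
#' Hash-style mixing of a master seed with an offset, giving independent,
#' reproducible seeds for the different stochastic stages of an analysis;
#' results stay below 2^31.
#'
#' @param seed master integer seed.
#' @param offset integer offset (scalar or vector) identifying the stage.
#' @return integer seed(s) of the same length as `offset`.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483647)
}
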