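# Monte Carlo performance metrics: absolute relative bias, simulated mean
# squared error, and simulated relative standard error.

#' Absolute relative bias (percent)
#'
#' `100 * |mean(estimates) - truth| / truth`, the absolute relative bias of
#' the Monte Carlo mean over replicates.
#'
#' @param estimates replicate estimates of a total.
#' @param truth the true total (positive).
#' @return ARB in percent.
#' @export
arb <- function(estimates, truth) {
  if (length(estimates) < 1L) stop("need at least one estimate", call. = FALSE)
  if (truth <= 0) stop("truth must be positive", call. = FALSE)
  100 * abs(mean(estimates) - truth) / truth
}

#' Simulated mean squared error
#'
#' Mean of squared deviations of the replicate estimates from the truth.
#'
#' @inheritParams arb
#' @return SMSE (same squared units as the total).
#' @export
smse <- function(estimates, truth) {
  if (length(estimates) < 1L) stop("need at least one estimate", call. = FALSE)
  mean((estimates - truth)^2)
}

#' Simulated relative standard error (percent)
#'
#' `100 * sqrt(smse_value) / truth`: the root of the simulated MSE, relative
#' to the true total, in percent.  Invariant to common rescaling of
#' estimates and truth.
#'
#' @param smse_value a simulated mean squared error (>= 0), see [smse()].
#' @param truth the true total (positive).
#' @return SRSE in percent.
#' @export
srse <- function(smse_value, truth) {
  if (smse_value < 0) stop("smse_value must be non-negative", call. = FALSE)
  if (truth <= 0) stop("truth must be positive", call. = FALSE)
  100 * sqrt(smse_value) / truth
}
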