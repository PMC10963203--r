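# Minimum chi-square calibration of design weights to domain auxiliary
# totals, under four q-weight systems, and the resulting domain estimators.
#
# For a stratum with base weights d, auxiliary values x and target total T,
# the chi-square-minimal calibrated weights are t = d * (1 + l * q * x) with
# l = (T - sum(d * x)) / sum(d * q * x^2).  q = 1/x gives the ratio system,
# q = 1 the regression (GREG) system.  The exponential system t = d*exp(l*x)
# and the power system t = d * eta^x arise from implicit, series-defined q;
# there the calibration constraint sum(t * x) = T is solved directly for the
# multiplier (Newton-Raphson), which is algebraically equivalent.

#' Explicit q-weights of the linear calibration systems
#'
#' @param x strictly positive auxiliary values.
#' @param policy `"unit"` (all ones; GREG) or `"inverse_x"` (1/x; ratio).
#'   The `"exponential"` and `"power"` systems have no closed-form q; request
#'   them through [calibrate_stratum()], which solves for the multiplier
#'   directly.
#' @return Numeric vector of q-weights.
#' @examples
#' q_weights(c(1, 2, 4), "inverse_x")   # 1, 0.5, 0.25
#' @export
q_weights <- function(x, policy = c("unit", "inverse_x")) {
  policy <- match.arg(policy, c("unit", "inverse_x", "exponential", "power"))
  if (policy %in% c("exponential", "power")) {
    stop("policy '", policy,
         "' is solved implicitly; use calibrate_stratum()", call. = FALSE)
  }
  if (any(x <= 0)) stop("auxiliary values must be strictly positive", call. = FALSE)
  switch(policy, unit = rep(1, length(x)), inverse_x = 1 / x)
}

#' Closed-form Lagrange multiplier of linear calibration
#'
#' Solves the chi-square-minimal calibration problem for the multiplier:
#' `l = (target - sum(d * x)) / sum(d * q * x^2)`.
#'
#' @param d base weights.
#' @param q q-weights (see [q_weights()]).
#' @param x auxiliary values.
#' @param target auxiliary total to calibrate to.
#' @return The multiplier `l` (0 when the target is already met).
#' @export
solve_linear_multiplier <- function(d, q, x, target) {
  denom <- sum(d * q * x^2)
  # negative base weights (possible after a previous linear calibration) can
  # make the denominator negative; only a vanishing denominator is degenerate
  if (!is.finite(denom) || denom == 0) {
    stop("degenerate calibration: sum(d * q * x^2) is zero", call. = FALSE)
  }
  (target - sum(d * x)) / denom
}

#' Linearly calibrated weights
#'
#' `t_i = d_i * (1 + l * q_i * x_i)`; with `l` from
#' [solve_linear_multiplier()], `sum(t * x)` equals the target to machine
#' precision.
#'
#' @inheritParams solve_linear_multiplier
#' @param l the multiplier.
#' @return Calibrated weight vector.
#' @export
linear_calibrated_weights <- function(d, q, x, l) {
  d * (1 + l * q * x)
}

#' Solve the exponential calibration multiplier
#'
#' Finds `l` such that `sum(d * x * exp(l * x)) = target` (the calibration
#' constraint of the weight system `t = d * exp(l * x)`).  The constraint
#' function is strictly increasing in `l`, so the root is unique; it is found
#' by Newton-Raphson from `l = 0` with the analytic derivative
#' `sum(d * x^2 * exp(l * x))`, safeguarded by bisection on a sign-bracketing
#' interval.  `x` is rescaled by its maximum internally (and `l` transformed
#' back) so that skewed auxiliaries cannot overflow `exp()`.
#'
#' @param d strictly positive base weights.
#' @param x strictly positive auxiliary values.
#' @param target positive auxiliary total.
#' @param tolerance relative residual tolerance on the constraint.
#' @param max_iter iteration cap.
#' @return List with `l`, `iterations`, `converged`, and the relative
#'   `residual` at exit.  Non-convergence within `max_iter`, or a target
#'   outside the bracketed range, signals an error with diagnostics.
#' @examples
#' solve_exponential_multiplier(1, 1, 2)$l   # log(2)
#' @export
solve_exponential_multiplier <- function(d, x, target,
                                         tolerance = 1e-10, max_iter = 100L) {
  if (any(d <= 0)) stop("base weights must be strictly positive", call. = FALSE)
  if (any(x <= 0)) stop("auxiliary values must be strictly positive", call. = FALSE)
  if (target <= 0) stop("target must be positive", call. = FALSE)
  xm <- max(x)
  u <- x / xm
  f <- function(m) sum(d * x * exp(m * u))
  # expand the bracket until it straddles the target: f decreases to 0 as
  # m -> -Inf and increases without bound, so a bracket always exists, but a
  # large dynamic range in x can need far more than the initial +/-50
  lo <- -50; hi <- 50
  tries <- 0L
  while (f(lo) > target && tries < 60L) { lo <- lo * 2; tries <- tries + 1L }
  while (f(hi) < target && tries < 120L) { hi <- hi * 2; tries <- tries + 1L }
  if (f(lo) - target > 0 || f(hi) - target < 0) {
    stop("exponential calibration target outside attainable range ",
         "[", format(f(lo)), ", ", format(f(hi)), "]", call. = FALSE)
  }
  m <- 0
  res <- f(m) - target
  it <- 0L
  while (abs(res) / target > tolerance && it < max_iter) {
    it <- it + 1L
    if (res > 0) hi <- m else lo <- m
    deriv <- sum(d * x * u * exp(m * u))
    m_new <- m - res / deriv
    if (!is.finite(m_new) || m_new <= lo || m_new >= hi) {
      m_new <- (lo + hi) / 2
    }
    m <- m_new
    res <- f(m) - target
  }
  if (abs(res) / target > tolerance) {
    stop("exponential calibration failed to converge: l = ", format(m / xm),
         ", relative residual = ", format(res / target), call. = FALSE)
  }
  list(l = m / xm, iterations = it, converged = TRUE,
       residual = abs(res) / target)
}

#' Solve the power calibration base
#'
#' Finds `eta > 0` such that `sum(d * x * eta^x) = target` (weight system
#' `t = d * eta^x`).  Since `eta^x = exp(log(eta) * x)`, this is the
#' exponential solve in `l = log(eta)`; the change of variables is exact.
#'
#' @inheritParams solve_exponential_multiplier
#' @return List with `eta`, `iterations`, `converged`, `residual`.
#' @examples
#' solve_power_parameter(1, 2, 8)$eta   # 2, since 2 * eta^2 = 8
#' @export
solve_power_parameter <- function(d, x, target,
                                  tolerance = 1e-10, max_iter = 100L) {
  sol <- solve_exponential_multiplier(d, x, target, tolerance, max_iter)
  list(eta = exp(sol$l), iterations = sol$iterations,
       converged = sol$converged, residual = sol$residual)
}

#' Calibrate one stratum's weights to an auxiliary target
#'
#' Dispatches on the q-weight policy: `"unit"` (GREG) and `"inverse_x"`
#' (ratio) use the closed-form multiplier; `"exponential"` and `"power"`
#' solve the constraint by Newton-Raphson.  Calibrated weights may be
#' negative under the linear policies (chi-square calibration does not bound
#' them); the count is reported, not suppressed.
#'
#' @param d base weights (strictly positive).
#' @param x auxiliary values (strictly positive).
#' @param target positive auxiliary total.
#' @param policy one of `"unit"`, `"inverse_x"`, `"exponential"`, `"power"`.
#' @param tolerance relative constraint tolerance for the iterative solvers.
#' @param max_iter iteration cap for the iterative solvers.
#' @return A `stratum_calibration` list: `t` (weights), `multiplier` (`l`,
#'   or `eta` for the power policy), `policy`, `iterations`, `converged`,
#'   `residual` (relative), `negative` (count of negative weights).
#' @export
calibrate_stratum <- function(d, x, target,
                              policy = c("unit", "inverse_x", "exponential", "power"),
                              tolerance = 1e-10, max_iter = 100L) {
  policy <- match.arg(policy)
  stopifnot(length(d) == length(x), length(d) >= 1L)
  if (target <= 0) stop("calibration target must be positive", call. = FALSE)
  if (policy %in% c("unit", "inverse_x")) {
    q <- q_weights(x, policy)
    l <- solve_linear_multiplier(d, q, x, target)
    t <- linear_calibrated_weights(d, q, x, l)
    out <- list(t = t, multiplier = l, policy = policy,
                iterations = 1L, converged = TRUE)
  } else if (policy == "exponential") {
    sol <- solve_exponential_multiplier(d, x, target, tolerance, max_iter)
    out <- list(t = d * exp(sol$l * x), multiplier = sol$l, policy = policy,
                iterations = sol$iterations, converged = sol$converged)
  } else {
    sol <- solve_power_parameter(d, x, target, tolerance, max_iter)
    out <- list(t = d * sol$eta^x, multiplier = sol$eta, policy = policy,
                iterations = sol$iterations, converged = sol$converged)
  }
  out$residual <- abs(sum(out$t * x) - target) / target
  out$negative <- sum(out$t < 0)
  class(out) <- "stratum_calibration"
  out
}

#' @export
print.stratum_calibration <- function(x, ...) {
  cat("Stratum calibration (", x$policy, "): multiplier = ",
      format(x$multiplier, digits = 8),
      ", iterations = ", x$iterations,
      ", relative residual = ", format(x$residual, digits = 3),
      if (x$negative > 0) paste0(", ", x$negative, " negative weight(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Weighted domain-total estimate
#'
#' `sum(t1 * y1) + sum(t2 * y2)` over the respondent sample and the
#' non-respondent subsample.  With `t = d` (base weights) this is the
#' Hansen-Hurwitz estimator.
#'
#' @param y1,t1 study values and weights of the respondent units.
#' @param y2,t2 study values and weights of the subsampled non-respondents
#'   (may be empty).
#' @return The estimated total.
#' @export
domain_estimate <- function(y1, t1, y2 = numeric(0), t2 = numeric(0)) {
  if (length(y1) != length(t1) || length(y2) != length(t2)) {
    stop("weights and study values are misaligned", call. = FALSE)
  }
  sum(t1 * y1) + sum(t2 * y2)
}

# Policy lookup shared by single-phase and two-phase estimation.
estimator_policy <- c(ratio = "inverse_x", greg = "unit",
                      exponential = "exponential", power = "power")

# Calibrate both strata of one domain and return the estimate plus
# diagnostics; errors from a solver are caught by the caller.
.calibrated_total <- function(d1, x1, y1, d2, x2, y2, X1a, X2a, policy,
                              tolerance, max_iter) {
  resp <- calibrate_stratum(d1, x1, X1a, policy, tolerance, max_iter)
  value <- sum(resp$t * y1)
  negative <- resp$negative
  converged <- resp$converged
  if (length(x2) > 0L) {
    nr <- calibrate_stratum(d2, x2, X2a, policy, tolerance, max_iter)
    value <- value + sum(nr$t * y2)
    negative <- negative + nr$negative
    converged <- converged && nr$converged
  }
  list(value = value, converged = converged, negative = negative)
}

#' All calibrated domain estimates for one sample realization
#'
#' For each domain, the base weights are re-calibrated to that domain's
#' respondent and non-respondent auxiliary totals `(X1a, X2a)` and the
#' calibrated weighted total of `y` is returned per estimator.  By default
#' the calibration and the estimate run over the *full* respondent sample and
#' the full non-respondent subsample (indirect, "borrow strength"
#' estimation); `scope = "direct"` restricts both to units falling in the
#' domain.
#'
#' Replicates with no sampled non-respondents use the respondent constraint
#' only and are flagged `degenerate`.  A solver failure in one
#' (domain, estimator) cell yields `NA` for that cell without aborting the
#' batch.  The `"base"` estimator is the uncalibrated Hansen-Hurwitz total;
#' it targets the population total and is reported once with `domain = NA`.
#'
#' @param r a `sample_realization` from [draw_sample()].
#' @param frame the `population_frame` sampled from.
#' @param totals a `domain_totals` table supplying `(X1a, X2a)` per domain.
#' @param estimators subset of `c("base", "ratio", "greg", "exponential",
#'   "power")`.
#' @param scope `"indirect"` (default) or `"direct"`.
#' @param tolerance,max_iter solver controls, see [calibrate_stratum()].
#' @return A `domain_estimates` data frame with columns `domain`,
#'   `estimator`, `value`, `converged`, `degenerate`, `negative_weights`.
#' @export
estimate_all <- function(r, frame, totals,
                         estimators = c("base", "ratio", "greg",
                                        "exponential", "power"),
                         scope = c("indirect", "direct"),
                         tolerance = 1e-10, max_iter = 100L) {
  stopifnot(inherits(r, "sample_realization"))
  frame <- as_population_frame(frame)
  totals <- as_domain_totals(totals)
  scope <- match.arg(scope)
  estimators <- match.arg(estimators, several.ok = TRUE)

  i1 <- match(r$s1, frame$unit_id)
  i2 <- match(r$s2r, frame$unit_id)
  y1 <- frame$y[i1]; x1 <- frame$x[i1]; dom1 <- frame$domain[i1]
  y2 <- frame$y[i2]; x2 <- frame$x[i2]; dom2 <- frame$domain[i2]
  d1 <- rep(r$d1, length(y1))
  d2 <- rep(r$d1 * r$d2prime, length(y2))

  rows <- list()
  if ("base" %in% estimators) {
    rows[[length(rows) + 1L]] <- data.frame(
      domain = NA_integer_, estimator = "base",
      value = sum(d1 * y1) + sum(d2 * y2),
      converged = TRUE, degenerate = r$n2 > 0L && r$n2r == 0L,
      negative_weights = 0L)
  }
  for (i in seq_len(nrow(totals))) {
    a <- totals$domain[i]
    X1a <- totals$X1a[i]; X2a <- totals$X2a[i]
    keep1 <- if (scope == "direct") dom1 == a else rep(TRUE, length(y1))
    keep2 <- if (scope == "direct") dom2 == a else rep(TRUE, length(y2))
    n1a <- sum(keep1); n2a <- sum(keep2)
    degenerate <- n2a == 0L
    for (est in setdiff(estimators, "base")) {
      if (n1a == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          domain = a, estimator = est, value = NA_real_,
          converged = FALSE, degenerate = TRUE, negative_weights = 0L)
        next
      }
      res <- tryCatch(
        .calibrated_total(d1[keep1], x1[keep1], y1[keep1],
                          d2[keep2], x2[keep2], y2[keep2],
                          X1a, X2a, estimator_policy[[est]],
                          tolerance, max_iter),
        error = function(e) list(value = NA_real_, converged = FALSE,
                                 negative = 0L))
      rows[[length(rows) + 1L]] <- data.frame(
        domain = a, estimator = est, value = res$value,
        converged = res$converged, degenerate = degenerate,
        negative_weights = res$negative)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("domain_estimates", "data.frame")
  out
}
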