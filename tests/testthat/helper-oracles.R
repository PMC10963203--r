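# Independent oracle formulas and small fixture builders used across tests.
# The oracles are coded directly from the explicit closed-form estimators,
# independently of the calibration path they are compared against.

# Explicit ratio-form estimator: stratum-wise weighted ratios expanded by the
# stratum auxiliary totals.
ratio_oracle <- function(d1, x1, y1, d2, x2, y2, X1a, X2a) {
  out <- sum(d1 * y1) / sum(d1 * x1) * X1a
  if (length(x2)) out <- out + sum(d2 * y2) / sum(d2 * x2) * X2a
  out
}

# Explicit regression-form (GREG) estimator: base total plus slope-corrected
# auxiliary gaps per stratum.
greg_oracle <- function(d1, x1, y1, d2, x2, y2, X1a, X2a) {
  a1 <- sum(d1 * x1 * y1) / sum(d1 * x1^2)
  out <- sum(d1 * y1) + a1 * (X1a - sum(d1 * x1))
  if (length(x2)) {
    a2 <- sum(d2 * x2 * y2) / sum(d2 * x2^2)
    out <- out + sum(d2 * y2) + a2 * (X2a - sum(d2 * x2))
  }
  out
}

# Pure bisection root of sum(d * x * exp(l * x)) = target, independent of the
# package's Newton solver.
bisect_exponential <- function(d, x, target, lo = -50, hi = 50, iters = 200) {
  f <- function(l) sum(d * x * exp(l * x)) - target
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Small two-domain population with fixed strata.
make_toy_frame <- function(seed = 42, noise = 0.2) {
  generate_population(population_spec(
    domain_sizes = c(18L, 12L), nonresponse_rate = 0.3,
    x_skew_shape = 0.8, link_slope = 2, noise_scale = noise, seed = seed))
}

# Fully responding single-stratum frame (no non-respondents), for census and
# full-response limits.
make_full_response_frame <- function(N = 40, seed = 7, noise = 0.25) {
  set.seed(seed)
  x <- rlnorm(N, 0, 0.8)
  data.frame(unit_id = seq_len(N),
             domain = rep(1:2, length.out = N),
             y = pmax(2 * x * (1 + rnorm(N, 0, noise)), 0),
             x = x,
             stratum = "R",
             stringsAsFactors = FALSE)
}

# Assemble a degenerate single-phase realization covering exactly the given
# respondent ids (used for census-limit comparisons).
respondents_only_realization <- function(ids, N) {
  structure(list(s = ids, s1 = ids, s2 = integer(0), s2r = integer(0),
                 n = length(ids), n1 = length(ids), n2 = 0L, n2r = 0L,
                 k = NA_real_, N = N, d1 = N / length(ids),
                 d2prime = NA_real_),
            class = "sample_realization")
}
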