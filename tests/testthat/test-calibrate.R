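test_that("q-weights implement the unit and inverse-x policies", {
  expect_equal(q_weights(c(1, 2, 4), "unit"), c(1, 1, 1))
  expect_equal(q_weights(c(1, 2, 4), "inverse_x"), c(1, 0.5, 0.25))
  expect_error(q_weights(c(1, 0, 2), "unit"), "strictly positive")
  expect_error(q_weights(c(1, 2), "exponential"), "calibrate_stratum")
})

test_that("linear multiplier and weights match the closed form by hand", {
  # d = (1,1), q = (1,1), x = (1,2), target = 4: l = (4-3)/(1+4) = 0.2,
  # t = (1.2, 1.4), sum(t*x) = 4 exactly
  l <- solve_linear_multiplier(c(1, 1), c(1, 1), c(1, 2), 4)
  expect_equal(l, 0.2)
  t <- linear_calibrated_weights(c(1, 1), c(1, 1), c(1, 2), l)
  expect_equal(t, c(1.2, 1.4))
  expect_identical(sum(t * c(1, 2)), 4)

  expect_equal(solve_linear_multiplier(c(2, 3), c(1, 1), c(1, 2), 2 + 6), 0)
  expect_error(solve_linear_multiplier(c(1, 1), c(0, 0), c(1, 2), 4), "zero")
})

test_that("exponential and power solvers recover closed forms and identities", {
  # single unit: exp(l) = 2 and 2 * eta^2 = 8
  expect_equal(solve_exponential_multiplier(1, 1, 2)$l, log(2), tolerance = 1e-10)
  expect_equal(solve_power_parameter(1, 2, 8)$eta, 2, tolerance = 1e-10)

  # consistent target gives the identity element exactly
  d <- c(1, 2); x <- c(1, 3)
  expect_identical(solve_exponential_multiplier(d, x, sum(d * x))$l, 0)
  expect_identical(solve_power_parameter(d, x, sum(d * x))$eta, 1)

  # strongly inflated target still converges (monotone constraint)
  sol <- solve_exponential_multiplier(c(1, 1), c(1, 3), 10 * 4)
  expect_true(sol$converged && sol$l > 0)
  expect_lte(sol$residual, 1e-10)

  # agreement with an independent bisection oracle, and eta = exp(l)
  set.seed(20)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    d <- runif(n, 0.5, 4); x <- rlnorm(n, 0, 1)
    target <- sum(d * x) * runif(1, 0.3, 3)
    l <- solve_exponential_multiplier(d, x, target)$l
    expect_equal(l, bisect_exponential(d, x, target), tolerance = 1e-9)
    expect_equal(solve_power_parameter(d, x, target)$eta, exp(l),
                 tolerance = 1e-10)
  }
})

test_that("every policy reproduces its auxiliary target", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    d <- runif(n, 1, 5); x <- rlnorm(n, 0, 1.2)
    target <- sum(d * x) * runif(1, 0.4, 2.5)
    for (pol in c("unit", "inverse_x", "exponential", "power")) {
      cal <- calibrate_stratum(d, x, target, pol)
      expect_true(cal$converged)
      expect_lte(cal$residual, 1e-8)
    }
  }
})

test_that("unit and inverse-x policies reduce to the explicit GREG and ratio forms", {
  set.seed(88)
  for (i in 1:25) {
    n1 <- sample(4:10, 1); n2 <- sample(2:6, 1)
    d1 <- rep(runif(1, 2, 4), n1); x1 <- rlnorm(n1); y1 <- 2 * x1 * runif(n1, 0.5, 1.5)
    d2 <- rep(d1[1] * runif(1, 1.2, 2), n2); x2 <- rlnorm(n2); y2 <- 2 * x2
    X1a <- sum(d1 * x1) * runif(1, 0.5, 1.5)
    X2a <- sum(d2 * x2) * runif(1, 0.5, 1.5)
    for (spec in list(list("inverse_x", ratio_oracle), list("unit", greg_oracle))) {
      c1 <- calibrate_stratum(d1, x1, X1a, spec[[1]])
      c2 <- calibrate_stratum(d2, x2, X2a, spec[[1]])
      got <- domain_estimate(y1, c1$t, y2, c2$t)
      want <- spec[[2]](d1, x1, y1, d2, x2, y2, X1a, X2a)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("ratio hand case: respondents only, proportional design weights", {
  # d = (1,1,1), y = (2,4,6), x = (1,2,3), X1a = 12: (12/6) * 12 = 24
  cal <- calibrate_stratum(c(1, 1, 1), c(1, 2, 3), 12, "inverse_x")
  expect_equal(domain_estimate(c(2, 4, 6), cal$t), 24)
})

test_that("consistent targets leave the base weights untouched", {
  d <- c(2, 3, 4); x <- c(1, 2, 0.5)
  for (pol in c("unit", "inverse_x", "exponential", "power")) {
    cal <- calibrate_stratum(d, x, sum(d * x), pol)
    expect_equal(cal$t, d)
  }
})

test_that("proportional populations are estimated exactly under every policy", {
  frame <- generate_population(population_spec(noise_scale = 0, seed = 31))
  tot <- summarize_domains(frame)
  r <- draw_sample(frame, 70, 12, seed = 32)
  est <- estimate_all(r, frame, tot)
  cal <- est[est$estimator != "base", ]
  expect_equal(cal$value, tot$Ya[match(cal$domain, tot$domain)],
               tolerance = 1e-9)
})

test_that("estimate_all handles degenerate and base cases", {
  frame <- make_full_response_frame()
  tot <- summarize_domains(frame)
  r <- draw_sample(frame, 12, 3, seed = 4)
  expect_equal(r$n2, 0L)
  est <- estimate_all(r, frame, tot)
  expect_true(all(est$degenerate[est$estimator != "base"]))
  expect_true(all(is.finite(est$value)))

  # base row equals the Hansen-Hurwitz total and carries no domain
  frame2 <- generate_population(population_spec(seed = 41))
  r2 <- draw_sample(frame2, 70, 12, seed = 42)
  est2 <- estimate_all(r2, frame2, summarize_domains(frame2))
  base <- est2[est2$estimator == "base", ]
  expect_true(is.na(base$domain))
  expect_equal(base$value, hh_total(r2, frame2))
  expect_true(all(is.finite(est2$value)))
})

test_that("misaligned estimate inputs are rejected", {
  expect_error(domain_estimate(c(1, 2), c(1, 1, 1)), "misaligned")
})
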