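test_that("phase-1 allocation, nesting, and determinism hold", {
  frame <- generate_population(population_spec(seed = 51))
  tp <- draw_two_phase(frame, 0.6, 70, 12, seed = 52)
  # round(0.6 * Na) per domain: (29, 19, 23, 25, 9, 17), total 122
  sizes <- tapply(tp$s1p, frame$domain[match(tp$s1p, frame$unit_id)], length)
  expect_equal(as.vector(sizes), c(29, 19, 23, 25, 9, 17))
  expect_equal(tp$n1p, 122L)
  expect_true(all(tp$s2p %in% tp$s1p))
  expect_true(all(tp$s11pp %in% tp$s11p))
  expect_true(all(tp$s12rpp %in% tp$s12rp))
  expect_true(all(tp$d11 >= 1))
  expect_equal(tp$d11pp, 122 / 70)
  expect_identical(tp, draw_two_phase(frame, 0.6, 70, 12, seed = 52))
  expect_error(draw_two_phase(frame, 0.6, 500, 12, seed = 1), "infeasible phase-2")
})

test_that("census phase 1 with full response recovers the true auxiliary totals", {
  frame <- make_full_response_frame(N = 40, seed = 61)
  tot <- summarize_domains(frame)
  tp <- draw_two_phase(frame, 1, 15, 5, seed = 62)
  tg <- phase1_targets(tp, frame)
  expect_equal(tg$x1a, tot$X1a)
  expect_equal(tg$x2a, rep(0, nrow(tot)))
  expect_true(all(tg$estimable))
})

test_that("phase-1 calibration reuses the linear closed-form algebra", {
  # two-unit census phase 1: d' = 1, x = (1, 2), target 4 -> multiplier 0.2,
  # weights (1.2, 1.4), as in the single-phase hand case
  frame <- data.frame(unit_id = 1:2, domain = 1L, y = c(1, 1), x = c(1, 2),
                      stratum = "R")
  tp <- draw_two_phase(frame, 1, 2, 1, seed = 1)
  p1 <- phase1_calibrate(tp, frame, x1a = 4, x2a = 0, policy = "unit")
  expect_equal(p1$resp$multiplier, 0.2)
  expect_equal(unname(p1$resp$t), c(1.2, 1.4))
})

test_that("degenerate phase 2 equal to phase 1 leaves the weights unchanged", {
  frame <- generate_population(population_spec(seed = 71))
  tp <- draw_two_phase(frame, 0.6, n_phase2 = 122, n2r_phase1 = 12,
                       n2r_phase2 = 12, seed = 72)
  expect_equal(tp$d11pp, 1)
  expect_equal(tp$k2, 1)
  tg <- phase1_targets(tp, frame)
  for (pol in c("unit", "inverse_x", "exponential", "power")) {
    p1 <- phase1_calibrate(tp, frame, tg$x1a[1], tg$x2a[1], pol)
    p2 <- phase2_calibrate(tp, frame, p1, tg$x1a[1], tg$x2a[1], pol)
    expect_equal(p2$resp$t[names(p1$resp$t)], p1$resp$t, tolerance = 1e-9)
    expect_equal(p2$nr$t[names(p1$nr$t)], p1$nr$t, tolerance = 1e-9)
  }
})

test_that("both phases satisfy their calibration constraints on random draws", {
  frame <- generate_population(population_spec(seed = 81))
  x_of <- function(ids) frame$x[match(ids, frame$unit_id)]
  for (seed in 82:84) {
    tp <- draw_two_phase(frame, 0.6, 70, 12, seed = seed)
    tg <- phase1_targets(tp, frame)
    for (pol in c("inverse_x", "unit", "exponential", "power")) {
      for (i in which(tg$estimable)) {
        p1 <- phase1_calibrate(tp, frame, tg$x1a[i], tg$x2a[i], pol)
        expect_lte(p1$resp$residual, 1e-8)
        if (!is.null(p1$nr)) expect_lte(p1$nr$residual, 1e-8)
        p2 <- phase2_calibrate(tp, frame, p1, tg$x1a[i], tg$x2a[i], pol)
        expect_lte(abs(sum(p2$resp$t * x_of(tp$s11pp)) - tg$x1a[i]) / tg$x1a[i],
                   1e-8)
        if (!is.null(p2$nr)) {
          expect_lte(abs(sum(p2$nr$t * x_of(tp$s12rpp)) - tg$x2a[i]) / tg$x2a[i],
                     1e-8)
        }
      }
    }
  }
})

test_that("proportional y passes exactly through both calibration phases", {
  frame <- generate_population(population_spec(noise_scale = 0, seed = 91))
  beta <- frame$y[1] / frame$x[1]
  tp <- draw_two_phase(frame, 0.6, 70, 12, seed = 92)
  tg <- phase1_targets(tp, frame)
  est <- two_phase_estimates(tp, frame)
  for (i in seq_len(nrow(tg))) {
    vals <- est$value[est$domain == tg$domain[i]]
    expect_equal(vals, rep(beta * (tg$x1a[i] + tg$x2a[i]), length(vals)),
                 tolerance = 1e-9)
  }
})

test_that("two-phase GREG matches an independent direct evaluation", {
  frame <- generate_population(population_spec(seed = 101))
  y_of <- function(ids) frame$y[match(ids, frame$unit_id)]
  x_of <- function(ids) frame$x[match(ids, frame$unit_id)]
  tp <- draw_two_phase(frame, 0.6, 70, 12, seed = 102)
  tg <- phase1_targets(tp, frame)
  est <- two_phase_estimates(tp, frame, "greg")
  for (i in seq_len(nrow(tg))) {
    p1 <- phase1_calibrate(tp, frame, tg$x1a[i], tg$x2a[i], "unit")
    b1 <- unname(p1$resp$t[as.character(tp$s11pp)]) * tp$d11pp
    b2 <- unname(p1$nr$t[as.character(tp$s12rpp)]) * tp$d11pp * tp$k2
    want <- greg_oracle(b1, x_of(tp$s11pp), y_of(tp$s11pp),
                        b2, x_of(tp$s12rpp), y_of(tp$s12rpp),
                        tg$x1a[i], tg$x2a[i])
    got <- est$value[est$domain == tg$domain[i]]
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("at a census first phase the two-phase ratio equals the single-phase ratio", {
  frame <- make_full_response_frame(N = 60, seed = 111)
  tot <- summarize_domains(frame)
  tp <- draw_two_phase(frame, 1, 20, 5, seed = 112)
  two <- two_phase_estimates(tp, frame, "ratio")
  r <- respondents_only_realization(tp$s2p, nrow(frame))
  one <- estimate_all(r, frame, tot, "ratio")
  expect_equal(two$value, one$value, tolerance = 1e-10)
})
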