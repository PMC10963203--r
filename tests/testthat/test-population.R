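test_that("packaged Swedish domain totals are loaded and internally consistent", {
  tot <- swedish_totals()
  expect_s3_class(tot, "domain_totals")
  expect_equal(nrow(tot), 6L)
  expect_equal(sum(tot$Na), 203L)
  expect_equal(tot$Ya[1], 142613)
  expect_equal(tot$Xa[1], 79618)
  expect_true(all(abs(tot$Ya - (tot$Y1a + tot$Y2a)) <= 0.5))
  expect_true(all(abs(tot$Xa - (tot$X1a + tot$X2a)) <= 0.5))
  expect_equal(tot$Na, tot$N1a + tot$N2a)
  expect_equal(nrow(validate_totals(tot)), 0L)
})

test_that("validate_totals flags perturbed tables without raising", {
  tot <- swedish_totals()
  tot$Y1a[1] <- tot$Y1a[1] + 10
  rep1 <- validate_totals(tot)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$domain, 1)

  tot2 <- swedish_totals()
  tot2$N1a[3] <- tot2$N1a[3] + 1L
  expect_true(any(grepl("N1a", validate_totals(tot2)$check)))
})

test_that("population_spec rejects infeasible configurations", {
  expect_error(population_spec(domain_sizes = c(10, 0)), "positive integers")
  expect_error(population_spec(nonresponse_rate = 0), "strictly in")
  expect_error(population_spec(nonresponse_rate = 1), "strictly in")
  # a 2-unit domain at 10% rounds to zero non-respondents
  expect_error(population_spec(domain_sizes = c(10, 2), nonresponse_rate = 0.1),
               "infeasible")
  expect_error(population_spec(noise_scale = -1), "non-negative")
})

test_that("generated populations honour sizes, strata, and determinism", {
  spec <- population_spec(seed = 5)
  frame <- generate_population(spec)
  expect_equal(nrow(frame), 203L)
  expect_true(all(frame$x > 0))
  expect_true(all(frame$y >= 0))

  # per-domain non-respondent counts are the half-up rounded rate, incl. the
  # 15-unit domain where 0.3 * 15 = 4.5 must give 5
  n2 <- tapply(frame$stratum == "NR", frame$domain, sum)
  expect_equal(as.vector(n2), c(14, 10, 11, 12, 5, 9))

  expect_identical(frame, generate_population(spec))
  frame2 <- generate_population(population_spec(seed = 6))
  expect_false(identical(frame$x, frame2$x))
})

test_that("generated auxiliary is right-skewed across many seeds", {
  skews <- vapply(1:100, function(s) {
    frame <- generate_population(population_spec(seed = s))
    m <- mean(frame$x)
    sd3 <- sqrt(mean((frame$x - m)^2))^3
    mean((frame$x - m)^3) / sd3
  }, numeric(1))
  expect_true(all(skews > 0))
})

test_that("target-total rescaling reproduces stratum totals exactly", {
  tot <- swedish_totals()
  frame <- generate_population(population_spec(target_totals = tot, seed = 9))
  got <- summarize_domains(frame)
  for (col in c("X1a", "X2a", "Y1a", "Y2a")) {
    expect_equal(got[[col]], tot[[col]], tolerance = 1e-6)
  }
})

test_that("summarize_domains is exact and additive", {
  one <- data.frame(unit_id = 1L, domain = 1L, y = 5, x = 2, stratum = "R")
  t1 <- summarize_domains(one)
  expect_equal(t1$Ya, 5); expect_equal(t1$Y1a, 5); expect_equal(t1$Y2a, 0)
  expect_equal(t1$Xa, 2); expect_equal(t1$X1a, 2)

  a <- make_toy_frame(seed = 1)
  b <- make_toy_frame(seed = 2)
  b$unit_id <- b$unit_id + max(a$unit_id)
  both <- summarize_domains(rbind(as.data.frame(a), as.data.frame(b)))
  ta <- summarize_domains(a); tb <- summarize_domains(b)
  for (col in setdiff(names(both), "domain")) {
    expect_equal(both[[col]], ta[[col]] + tb[[col]])
  }
  # computed totals satisfy the identities exactly
  expect_equal(ta$Ya, ta$Y1a + ta$Y2a)
  expect_equal(ta$Xa, ta$X1a + ta$X2a)
})

test_that("population and totals CSV dialects round-trip", {
  frame <- make_toy_frame(seed = 3)
  fp <- tempfile(fileext = ".csv")
  write_population(frame, fp)
  back <- read_population(fp)
  expect_equal(as.data.frame(back), as.data.frame(frame), tolerance = 1e-12)

  tot <- summarize_domains(frame)
  tp <- tempfile(fileext = ".csv")
  write_domain_totals(tot, tp)
  expect_equal(as.data.frame(read_domain_totals(tp)), as.data.frame(tot))
})
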