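test_that("toy dataset reproduces hand-derived estimates to 1e-9", {
  ss <- sums_of_squares(toy_data())
  expect_equal(ss$SSA, 6.25, tolerance = 1e-9)
  expect_equal(ss$SSB, 2.25, tolerance = 1e-9)
  expect_equal(ss$SSE, 0.25, tolerance = 1e-9)
  expect_identical(c(ss$nu_A, ss$nu_B, ss$nu_E), c(1L, 1L, 1L))
  expect_identical(ss$N, 4L)

  vc <- variance_components(ss)
  expect_equal(vc$sigma2_A, 3.0, tolerance = 1e-9)
  expect_equal(vc$sigma2_B, 1.0, tolerance = 1e-9)
  expect_equal(vc$sigma2_E, 0.25, tolerance = 1e-9)
  expect_false(any(vc$negative))

  expect_equal(loam_estimate(ss), 1.96 * sqrt(2.5 / 4), tolerance = 1e-12)
  expect_equal(loam_estimate(ss), 1.54951605348, tolerance = 1e-9)
  expect_equal(jones_loam(ss), 0.98, tolerance = 1e-9)
  expect_equal(as.numeric(icc_a1(vc)), 3 / 4.25, tolerance = 1e-12)
})

test_that("identical values give zero sums of squares and zero limits", {
  d <- agreement_data(rep(c("s1", "s2", "s3"), each = 2),
                      rep(c("o1", "o2"), 3), rep(7, 6))
  ss <- sums_of_squares(d)
  expect_equal(c(ss$SSA, ss$SSB, ss$SSE), c(0, 0, 0))
  expect_equal(loam_estimate(ss), 0)
  expect_equal(jones_loam(ss), 0)
  expect_error(icc_a1(variance_components(ss)), "degenerate")
})

test_that("sums of squares agree with a brute-force loop oracle", {
  set.seed(202)
  for (i in 1:15) {
    d <- random_balanced(a = sample(3:8, 1), b = sample(2:6, 1),
                         c = sample(1:3, 1))
    ss <- sums_of_squares(d)
    bf <- brute_force_ss(d)
    expect_equal(ss$SSA, bf$SSA, tolerance = 1e-9)
    expect_equal(ss$SSB, bf$SSB, tolerance = 1e-9)
    expect_equal(ss$SSE, bf$SSE, tolerance = 1e-9)
  }
})

test_that("decomposition and within-subject identities hold on random data", {
  set.seed(303)
  for (i in 1:25) {
    d <- random_balanced(a = sample(2:10, 1), b = sample(2:8, 1),
                         c = sample(1:3, 1))
    ss <- sums_of_squares(d)
    tot <- sum((d$value - mean(d$value))^2)
    expect_equal(ss$SSA + ss$SSB + ss$SSE, tot, tolerance = 1e-9)
    mi <- tapply(d$value, d$subject, mean)
    expect_equal(ss$SSB + ss$SSE, sum((d$value - mi[d$subject])^2),
                 tolerance = 1e-9)
    expect_identical(ss$nu_A + ss$nu_B + ss$nu_E, ss$N - 1L)
  }
})

test_that("estimates are translation invariant and scale equivariant", {
  set.seed(404)
  d <- random_balanced(a = 6, b = 4, c = 2)
  ss <- sums_of_squares(d)
  shift <- agreement_data(d$subject, d$observer, d$value + 123.4, d$replicate)
  ss_shift <- sums_of_squares(shift)
  expect_equal(c(ss_shift$SSA, ss_shift$SSB, ss_shift$SSE),
               c(ss$SSA, ss$SSB, ss$SSE), tolerance = 1e-8)
  expect_equal(loam_estimate(ss_shift), loam_estimate(ss), tolerance = 1e-9)
  expect_equal(as.numeric(icc_a1(variance_components(ss_shift))),
               as.numeric(icc_a1(variance_components(ss))), tolerance = 1e-9)

  lam <- 2.5
  sc <- agreement_data(d$subject, d$observer, lam * d$value, d$replicate)
  ss_sc <- sums_of_squares(sc)
  expect_equal(loam_estimate(ss_sc), lam * loam_estimate(ss),
               tolerance = 1e-9)
  expect_equal(jones_loam(ss_sc), lam * jones_loam(ss), tolerance = 1e-9)
  expect_equal(as.numeric(icc_a1(variance_components(ss_sc))),
               as.numeric(icc_a1(variance_components(ss))), tolerance = 1e-9)
})

test_that("replicated formulas reduce to the single-measurement case at c=1", {
  set.seed(505)
  d <- random_balanced(a = 7, b = 5, c = 1)
  ss <- sums_of_squares(d)
  a <- 7L; b <- 5L
  # single-measurement definitions, written out directly
  expect_identical(ss$nu_E, (a - 1L) * (b - 1L))
  gm <- mean(d$value)
  mj <- tapply(d$value, d$observer, mean)
  expect_equal(ss$SSB, a * sum((mj - gm)^2), tolerance = 1e-9)
  vc <- variance_components(ss)
  expect_equal(vc$sigma2_B, (ss$MSB - ss$MSE) / a, tolerance = 1e-12)
  expect_equal(vc$sigma2_A, (ss$MSA - ss$MSE) / b, tolerance = 1e-12)
})

test_that("negative variance estimates are returned signed and flagged", {
  # equal observer means but nonzero residual: SSB = 0 forces sigma2_B < 0
  d <- agreement_data(rep(c("s1", "s2", "s3"), each = 2),
                      rep(c("o1", "o2"), 3),
                      c(1, 2, 2, 1, 5, 5))
  vc <- variance_components(sums_of_squares(d))
  expect_lt(vc$sigma2_B, 0)
  expect_true(vc$negative["B"])
  expect_false(vc$negative["A"])
  icc <- icc_a1(vc)
  expect_true(is.finite(icc))
})

test_that("pure subject effects give ICC(A,1) of exactly one", {
  d <- agreement_data(c("s1", "s1", "s2", "s2"),
                      c("o1", "o2", "o1", "o2"),
                      c(1, 1, 2, 2))
  vc <- variance_components(sums_of_squares(d))
  expect_equal(vc$sigma2_B, 0)
  expect_equal(vc$sigma2_E, 0)
  expect_equal(as.numeric(icc_a1(vc)), 1)
})

test_that("population LOAM matches the closed form and its Monte Carlo check", {
  expect_equal(loam_population(0, 0, b = 4), 0)
  expect_equal(loam_population(0.25, 0.75, b = 4), 1.96 * sqrt(0.75),
               tolerance = 1e-12)
  expect_equal(loam_population(0.25, 0.75, b = 4), 1.69740979142,
               tolerance = 1e-9)
  expect_error(loam_population(-0.1, 0.5, b = 3), "nonnegative")

  # fraction of differences D_ij within the population limits ~ 95%
  set.seed(606)
  lim <- loam_population(0.3^2, 0.6^2, b = 6)
  hits <- replicate(400, {
    d <- simulate_loam_data(a = 10, b = 6, mu = 5, sigma_A = 2,
                            sigma_B = 0.3, sigma_E = 0.6)
    mi <- tapply(d$value, d$subject, mean)
    dd <- d$value - mi[d$subject]
    mean(abs(dd) <= lim)
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.01)
})

test_that("ANOVA moment estimates agree with REML on balanced data", {
  set.seed(707)
  d <- simulate_loam_data(a = 30, b = 8, c = 2, mu = 10,
                          sigma_A = 3, sigma_B = 1, sigma_E = 0.8)
  vc <- variance_components(sums_of_squares(d))
  fit <- lme4::lmer(value ~ 1 + (1 | subject) + (1 | observer),
                    data = as.data.frame(d), REML = TRUE)
  vcr <- as.data.frame(lme4::VarCorr(fit))
  reml <- stats::setNames(vcr$vcov, vcr$grp)
  expect_equal(vc$sigma2_A, unname(reml["subject"]), tolerance = 1e-5)
  expect_equal(vc$sigma2_B, unname(reml["observer"]), tolerance = 1e-5)
  expect_equal(vc$sigma2_E, unname(reml["Residual"]), tolerance = 1e-5)
})
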