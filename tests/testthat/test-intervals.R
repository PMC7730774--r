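test_that("Graybill-Wang LOAM interval matches hand evaluation on the toy data", {
  ss <- sums_of_squares(toy_data())
  iv <- loam_ci(ss)
  # frozen from direct evaluation: l = 1 - 1/(qchisq(.975,1)/1),
  # h = 1/(qchisq(.025,1)/1) - 1, L/H = mult * sqrt(SSB^2+SSE^2)
  expect_equal(iv$lower, 0.812141716322, tolerance = 1e-9)
  expect_equal(iv$upper, 47.0544563956, tolerance = 1e-7)
  expect_equal(iv$point, loam_estimate(ss), tolerance = 1e-12)
  expect_identical(iv$method, "graybill_wang")
})

test_that("degenerate data give a degenerate LOAM interval", {
  ss <- make_ss(SSA = 0, SSB = 0, SSE = 0, a = 3, b = 3)
  iv <- loam_ci(ss)
  expect_equal(c(iv$lower, iv$point, iv$upper), c(0, 0, 0))
})

test_that("exact chi-square interval for sigma_E matches hand evaluation", {
  ss <- sums_of_squares(toy_data())
  iv <- sigma_E_ci(ss)
  expect_equal(iv$point, 0.5, tolerance = 1e-12)
  expect_equal(iv$lower, 0.22307459246, tolerance = 1e-9)
  expect_equal(iv$upper, 15.9550796748, tolerance = 1e-7)
  expect_identical(iv$method, "chi_square_exact")

  ss0 <- make_ss(SSB = 1, SSE = 0, a = 3, b = 3)
  iv0 <- sigma_E_ci(ss0)
  expect_equal(c(iv0$lower, iv0$point, iv0$upper), c(0, 0, 0))
})

test_that("delta-method intervals for sigma_B and sigma_A match hand values", {
  ss <- sums_of_squares(toy_data())
  vc <- variance_components(ss)
  ivB <- sigma_B_ci(vc, ss)
  expect_equal(ivB$point, 1.0, tolerance = 1e-12)
  expect_equal(ivB$upper - ivB$point, 1.56876543817, tolerance = 1e-9)
  expect_equal(ivB$point - ivB$lower, ivB$upper - ivB$point,
               tolerance = 1e-12)  # symmetric, lower may be negative
  expect_lt(ivB$lower, 0)

  ivA <- sigma_A_ci(vc, ss)
  expect_equal(ivA$point, sqrt(3), tolerance = 1e-12)
  expect_equal(ivA$upper - ivA$point, 2.50252039619, tolerance = 1e-9)
})

test_that("nonpositive variance estimates flag the delta intervals undefined", {
  d <- agreement_data(rep(c("s1", "s2", "s3"), each = 2),
                      rep(c("o1", "o2"), 3),
                      c(1, 2, 2, 1, 5, 5))  # SSB = 0 => sigma2_B < 0
  ss <- sums_of_squares(d)
  vc <- variance_components(ss)
  iv <- sigma_B_ci(vc, ss)
  expect_true(all(c("undefined", "negative_component") %in% iv$flags))
  expect_true(is.na(iv$lower) && is.na(iv$upper))
})

test_that("replicated designs use the a->ac and b->bc substitutions", {
  set.seed(810)
  d <- random_balanced(a = 8, b = 4, c = 3)
  ss <- sums_of_squares(d)
  vc <- variance_components(ss)
  z <- 1.96
  hwB <- z / (8 * 3 * sqrt(vc$sigma2_B)) *
    sqrt((8 * 3 * vc$sigma2_B + vc$sigma2_E)^2 / (2 * ss$nu_B) +
           vc$sigma2_E^2 / (2 * ss$nu_E))
  ivB <- sigma_B_ci(vc, ss)
  expect_equal(ivB$upper - ivB$point, hwB, tolerance = 1e-12)
  hwA <- z / (4 * 3 * sqrt(vc$sigma2_A)) *
    sqrt((4 * 3 * vc$sigma2_A + vc$sigma2_E)^2 / (2 * ss$nu_A) +
           vc$sigma2_E^2 / (2 * ss$nu_E))
  ivA <- sigma_A_ci(vc, ss)
  expect_equal(ivA$upper - ivA$point, hwA, tolerance = 1e-12)
})

test_that("LOAM interval lower bound is real, nonnegative, and brackets the point", {
  set.seed(909)
  for (i in 1:50) {
    SSB <- rexp(1, 1 / 5); SSE <- rexp(1, 1 / 5)
    a <- sample(2:20, 1); b <- sample(2:20, 1); cc <- sample(1:3, 1)
    ss <- make_ss(SSB = SSB, SSE = SSE, a = a, b = b, c = cc)
    iv <- loam_ci(ss)
    expect_gte(iv$lower, 0)
    expect_lte(iv$lower, iv$point)
    expect_gte(iv$upper, iv$point)
    ivE <- sigma_E_ci(ss)
    expect_lte(ivE$lower, ivE$point)
    expect_gte(ivE$upper, ivE$point)
  }
})

test_that("ICC(A,1) interval reduces to the published single-measurement formula", {
  # independent transcription of the absolute-agreement single-score CI
  mw_icc_ci <- function(MSR, MSC, MSE, n, k, alpha = 0.05) {
    r <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    aa <- k * r / (n * (1 - r))
    bb <- 1 + k * r * (n - 1) / (n * (1 - r))
    v <- (aa * MSC + bb * MSE)^2 /
      ((aa * MSC)^2 / (k - 1) + (bb * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    c(r = r,
      lower = n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR),
      upper = n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR))
  }
  set.seed(111)
  for (i in 1:10) {
    a <- sample(8:20, 1); b <- sample(3:8, 1)
    d <- random_balanced(a = a, b = b, c = 1)
    ss <- sums_of_squares(d)
    iv <- icc_ci(ss)
    ref <- mw_icc_ci(ss$MSA, ss$MSB, ss$MSE, n = a, k = b)
    expect_equal(iv$point, unname(ref["r"]), tolerance = 1e-9)
    expect_equal(iv$lower, unname(ref["lower"]), tolerance = 1e-9)
    expect_equal(iv$upper, unname(ref["upper"]), tolerance = 1e-9)
  }
})

test_that("ICC interval tends to (1, 1) as observer and residual variation vanish", {
  set.seed(222)
  d <- simulate_loam_data(a = 20, b = 5, mu = 0, sigma_A = 2,
                          sigma_B = 1e-5, sigma_E = 1e-5)
  iv <- icc_ci(sums_of_squares(d))
  expect_gt(iv$lower, 0.999)
  expect_gt(iv$point, 0.9999)
  expect_lte(iv$upper, 1 + 1e-9)
})

test_that("ICC interval is flagged undefined outside [0, 1)", {
  # equal subject means but distinct observer means: SSA = 0 => ICC < 0
  d <- agreement_data(c("s1", "s1", "s2", "s2"),
                      c("o1", "o2", "o1", "o2"),
                      c(1, 2, 0, 3))
  iv <- icc_ci(sums_of_squares(d))
  expect_lt(iv$point, 0)
  expect_true("undefined" %in% iv$flags)
})

test_that("loam_level and level act independently", {
  ss <- sums_of_squares(toy_data())
  iv90 <- loam_ci(ss, level = 0.90, loam_level = 0.95)
  iv95 <- loam_ci(ss, level = 0.95, loam_level = 0.95)
  expect_equal(iv90$point, iv95$point)          # same limits
  expect_lt(iv95$lower, iv90$lower)             # wider CI at higher level
  expect_gt(iv95$upper, iv90$upper)

  iv80 <- loam_ci(ss, level = 0.95, loam_level = 0.80)
  expect_equal(iv80$point / iv95$point, loam_z(0.80) / 1.96,
               tolerance = 1e-12)
})
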