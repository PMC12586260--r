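# Agreement statistics: r, MD(SD), MAE/RMSE, SMD, bootstrap CIs,
# Bland-Altman limits.

test_that("identity and constant-shift cases fix the sign conventions", {
  set.seed(26)
  o <- rnorm(50, 45, 8)
  a0 <- score_agreement(o, o, B = 0)$overall
  expect_equal(a0$pearson_r, 1)
  expect_equal(a0$mean_diff, 0)
  expect_equal(a0$mae, 0)
  expect_equal(a0$rmse, 0)
  expect_equal(a0$smd, 0)
  # linked = observed + 2: MD = observed - linked = -2
  a2 <- score_agreement(o, o + 2, B = 0)$overall
  expect_equal(a2$mean_diff, -2, tolerance = 1e-12)
  expect_equal(a2$mae, 2, tolerance = 1e-12)
  expect_equal(a2$rmse, 2, tolerance = 1e-12)
  expect_equal(a2$sd_diff, 0, tolerance = 1e-12)
})

test_that("pooled-SD paired SMD reproduces published-style summary cells", {
  expect_equal(round_half_up(smd_from_summary(-0.11, 8.66, 10.30)), -0.01)
  expect_equal(round_half_up(smd_from_summary(-1.62, 8.98, 8.72)), -0.18)
  expect_equal(smd_from_summary(0, 3, 3), 0)
  expect_error(smd_from_summary(1, 0, 2), "positive")
})

test_that("|SMD| is invariant to exchanging the two score sets", {
  set.seed(27)
  a <- rnorm(80, 42, 9)
  b <- rnorm(80, 44, 8)
  expect_equal(smd_from_summary(mean(a - b), sd(a), sd(b)),
               -smd_from_summary(mean(b - a), sd(b), sd(a)),
               tolerance = 1e-12)
})

test_that("the RMSE-MD-SD identity holds on every report", {
  set.seed(28)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    o <- rnorm(n, 43, 9)
    l <- o + rnorm(n, -0.5, 3)
    a <- score_agreement(o, l, B = 0)$overall
    expect_equal(a$rmse^2, a$mean_diff^2 + a$sd_diff^2 * (n - 1) / n,
                 tolerance = 1e-9)
    expect_gte(a$rmse, a$mae)
  }
  # cross-check against a printed-style triple: MD 0.11, SD 4.83, n 619
  expect_equal(sqrt(0.11^2 + 4.83^2 * 618 / 619), 4.83, tolerance = 5e-3)
})

test_that("bootstrap CIs are deterministic, degenerate-safe, and calibrated", {
  set.seed(29)
  o <- rnorm(60, 40, 7)
  l <- o + rnorm(60, 0, 3)
  ci1 <- bootstrap_ci(o, l, "mae", B = 400, seed = 5)
  ci2 <- bootstrap_ci(o, l, "mae", B = 400, seed = 5)
  expect_identical(ci1, ci2)
  # all differences identical: interval collapses to the point estimate
  d <- rnorm(30)
  cid <- bootstrap_ci(d + 1.3, d, "mae", B = 300, seed = 6)
  expect_equal(cid[1], 1.3, tolerance = 1e-12)
  expect_equal(cid[2], 1.3, tolerance = 1e-12)
  expect_error(bootstrap_ci(o, l, "mae", B = 100, seed = 1), ">= 200")
  expect_error(bootstrap_ci(o, l, "mae", B = 300), "seed")

  # coverage of the analytic MAE of N(0,1) differences, sqrt(2/pi)
  target <- sqrt(2 / pi)
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    diffs <- rnorm(500)
    ci <- bootstrap_ci(diffs, rep(0, 500), "mae", B = 400, seed = s)
    if (ci[1] <= target && target <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("bootstrap CI width shrinks with sample size", {
  set.seed(30)
  o8 <- rnorm(800, 43, 9)
  l8 <- o8 + rnorm(800, 0, 4)
  w8 <- diff(bootstrap_ci(o8, l8, "rmse", B = 500, seed = 9))
  i <- 1:200
  w2 <- diff(bootstrap_ci(o8[i], l8[i], "rmse", B = 500, seed = 9))
  expect_lt(w8, w2)
})

test_that("Bland-Altman limits and trends behave on stylized inputs", {
  set.seed(31)
  o <- rnorm(40, 45, 8)
  # identity: zero MD, zero-width limits, flat trend
  ba0 <- bland_altman(o, o)
  expect_equal(ba0$summary$md, 0)
  expect_equal(ba0$summary$loa_lower, 0)
  expect_equal(ba0$summary$loa_upper, 0)
  expect_equal(ba0$summary$trend_slope, 0, tolerance = 1e-12)
  # printed-style arithmetic: MD -1.19, SD 4.37 -> (-9.76, 7.38)
  expect_equal(round_half_up(-1.19 - 1.96 * 4.37), -9.76)
  expect_equal(round_half_up(-1.19 + 1.96 * 4.37), 7.38)
  # antisymmetric perturbation: MD 0, symmetric limits
  d <- rep(c(2, -2), each = 20)
  ba1 <- bland_altman(o + d, o)
  expect_equal(ba1$summary$md, 0, tolerance = 1e-12)
  expect_equal(ba1$summary$loa_lower, -ba1$summary$loa_upper,
               tolerance = 1e-12)
  # a tiny subsample gets no trend line
  ba2 <- bland_altman(o, o + rnorm(40), subsample = c(rep("big", 38),
                                                      "small", "small"))
  expect_true(ba2$summary$trend_omitted[ba2$summary$subsample == "small"])
  expect_false(ba2$summary$trend_omitted[ba2$summary$subsample == "big"])
})

test_that("zero-variance vectors are reported as missing correlation", {
  o <- rep(42, 10)
  l <- rnorm(10, 42, 2)
  a <- score_agreement(l, o, B = 0)$overall
  expect_true(is.na(a$pearson_r))
  expect_true(a$zero_variance)
})

test_that("per-subsample breakdowns are computed alongside the overall report", {
  set.seed(32)
  o <- rnorm(90, 43, 8)
  l <- o + rnorm(90, -1, 3)
  lab <- rep(c("cardiology", "rheumatology", "psychosomatic"), each = 30)
  a <- score_agreement(o, l, lab, B = 200, seed = 3)
  expect_named(a$by_subsample,
               c("cardiology", "rheumatology", "psychosomatic"))
  expect_equal(a$overall$n, 90)
  expect_equal(a$by_subsample$cardiology$n, 30)
  expect_length(a$overall$ci_mae, 2L)
  expect_lt(a$overall$ci_mae[1], a$overall$mae)
  expect_gt(a$overall$ci_mae[2], a$overall$mae)
})
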