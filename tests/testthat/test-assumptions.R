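# Dimensionality diagnostics and DIF screening.

test_that("the internal bivariate normal CDF matches an integration oracle", {
  cases <- expand.grid(h = c(-1.5, 0, 0.8), k = c(-0.4, 1.2),
                       rho = c(-0.95, -0.3, 0.3, 0.6, 0.95))
  for (i in seq_len(nrow(cases))) {
    got <- pfcrosslink:::pbvnorm(cases$h[i], cases$k[i], cases$rho[i])
    want <- pbvnorm_oracle(cases$h[i], cases$k[i], cases$rho[i])
    expect_equal(got, want, tolerance = 1e-8)
  }
  # boundary conventions
  expect_equal(pfcrosslink:::pbvnorm(Inf, 0.3, 0.5), pnorm(0.3),
               tolerance = 1e-12)
  expect_equal(pfcrosslink:::pbvnorm(0.3, -Inf, 0.5), 0, tolerance = 1e-12)
})

test_that("polychoric estimates recover generating correlations", {
  set.seed(14)
  n <- 5000
  # duplicated column: rho = 1
  x <- sample.int(3, n, replace = TRUE)
  R <- polychoric_matrix(cbind(a = x, b = x))
  expect_equal(R[1, 2], 1, tolerance = 1e-6)
  # independence: |rho| < 0.05
  y <- sample.int(4, n, replace = TRUE)
  R0 <- polychoric_matrix(cbind(a = x, b = y))
  expect_lt(abs(R0[1, 2]), 0.05)
  # discretized bivariate normal with rho = 0.6
  z1 <- rnorm(n)
  z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
  o1 <- cut(z1, c(-Inf, -0.6, 0.4, Inf), labels = FALSE)
  o2 <- cut(z2, c(-Inf, -1, 0, 1, Inf), labels = FALSE)
  R6 <- polychoric_matrix(cbind(a = o1, b = o2))
  expect_lt(abs(R6[1, 2] - 0.6), 0.04)
  expect_identical(diag(R6), c(a = 1, b = 1))
})

test_that("a constant column falls back to Spearman with a warning", {
  x <- c(rep(1L, 50), 2L)
  y <- sample.int(3, 51, replace = TRUE)
  # x has 2 categories but pair them with a truly constant column
  expect_warning(R <- polychoric_matrix(cbind(a = rep(1L, 51), b = y)),
                 "fallback")
  expect_true(is.na(R[1, 2]) || abs(R[1, 2]) <= 1)
})

test_that("one-factor ULS fit: perfect, good, and poor structures", {
  # model-implied matrix fed back: perfect fit
  l <- seq(0.55, 0.85, length.out = 12)
  Rp <- tcrossprod(l)
  diag(Rp) <- 1
  f <- one_factor_fit(Rp, 600)
  expect_equal(f$fit$srmr, 0, tolerance = 1e-6)
  expect_equal(f$fit$cfi, 1, tolerance = 1e-9)
  expect_equal(f$fit$rmsea, 0, tolerance = 1e-6)
  expect_equal(abs(f$loadings), l, tolerance = 1e-4, ignore_attr = TRUE)

  # sampled one-factor ordinal data passes the conventional benchmarks
  set.seed(15)
  th <- rnorm(600)
  bank <- lapply(1:30, function(j)
    item_parameters(sprintf("i%02d", j), runif(1, 1.4, 3),
                    sort(runif(1, -1.5, 0.5) + c(-0.6, 0.6))))
  v <- simulate_grm_responses(bank, th, seed = 16)
  R <- polychoric_matrix(v)
  f1 <- one_factor_fit(R, 600)
  expect_gt(f1$fit$cfi, 0.95)
  expect_lt(f1$fit$srmr, 0.08)
  expect_true(f1$benchmark_flags$cfi)

  # two orthogonal factors, loadings 0.8: fails the CFI benchmark
  L2 <- matrix(0, 16, 2)
  L2[1:8, 1] <- 0.8
  L2[9:16, 2] <- 0.8
  R2 <- tcrossprod(L2)
  diag(R2) <- 1
  f2 <- one_factor_fit(R2, 600)
  expect_lt(f2$fit$cfi, 0.95)
})

test_that("fit indices are invariant to item order", {
  set.seed(17)
  th <- rnorm(400)
  bank <- lapply(1:12, function(j)
    item_parameters(sprintf("i%02d", j), runif(1, 1.4, 2.8),
                    c(-0.7, 0.5) + runif(1, -0.5, 0.5)))
  v <- simulate_grm_responses(bank, th, seed = 18)
  R <- polychoric_matrix(v)
  perm <- sample(ncol(R))
  f_a <- one_factor_fit(R, 400)
  f_b <- one_factor_fit(R[perm, perm], 400)
  expect_equal(f_a$fit$cfi, f_b$fit$cfi, tolerance = 1e-6)
  expect_equal(f_a$fit$srmr, f_b$fit$srmr, tolerance = 1e-6)
})

test_that("bifactor indices separate general-factor from group-factor structure", {
  # strong general factor only
  l <- runif(30, 0.6, 0.85)
  Rg <- tcrossprod(l)
  diag(Rg) <- 1
  bg <- bifactor_ecv_omega(Rg, 600, 4)
  expect_gt(bg$ecv, 0.9)
  # orthogonal group factors, no general factor
  L <- matrix(0, 32, 4)
  for (f in 1:4) L[(f - 1) * 8 + 1:8, f] <- 0.8
  Ro <- tcrossprod(L)
  diag(Ro) <- 1
  bo <- bifactor_ecv_omega(Ro, 600, 4)
  expect_lt(bo$ecv, 0.2)
  # both always inside [0, 1]
  for (b in list(bg, bo)) {
    expect_gte(b$ecv, 0)
    expect_lte(b$ecv, 1)
    expect_gte(b$omega_h, 0)
    expect_lte(b$omega_h, 1)
  }
  expect_error(bifactor_ecv_omega(Rg, 600, 12), "too many")
})

test_that("DIF screen is quiet under the null and catches planted DIF", {
  set.seed(19)
  n <- 1000
  th <- rnorm(n)
  grp <- factor(sample(c("a", "b"), n, replace = TRUE))
  bank <- lapply(1:10, function(j)
    item_parameters(sprintf("i%02d", j), runif(1, 1.3, 2.8),
                    runif(1, -1.2, 0.4) + c(-0.8, 0.8), "linked"))
  v <- simulate_grm_responses(bank, th, seed = 20)
  d0 <- dif_screen(v, grp, th)
  expect_true(all(d0$delta_r2 >= 0))
  expect_true(all(d0$r2_m3 >= d0$r2_m1 - 1e-10))
  expect_lte(sum(d0$flagged, na.rm = TRUE), 1L)

  # plant uniform DIF of 1.0 on item 1's thresholds for group b
  bank_b <- bank
  bank_b[[1]] <- item_parameters("i01", bank[[1]]$a, bank[[1]]$b + 1,
                                 "linked")
  vb <- v
  ib <- grp == "b"
  vb[ib, ] <- simulate_grm_responses(bank_b, th[ib], seed = 21)
  d1 <- dif_screen(vb, grp, th)
  expect_true(d1$flagged[1])
  expect_gt(d1$delta_r2[1], 0.03)

  expect_error(dif_screen(v, factor(rep("a", n)), th), "two levels")
  expect_error(dif_screen(v, grp, rep(NA_real_, n)), "finite")
})

test_that("null DIF flag rate stays at or below 5% across seeds", {
  rates <- vapply(c(23, 24, 25), function(s) {
    set.seed(s)
    n <- 619
    th <- rnorm(n)
    grp <- factor(sample(c("x", "y"), n, replace = TRUE))
    bank <- lapply(1:10, function(j)
      item_parameters(sprintf("i%02d", j), runif(1, 1.3, 2.8),
                      runif(1, -1.2, 0.4) + c(-0.8, 0.8)))
    v <- simulate_grm_responses(bank, th, seed = s + 100)
    d <- dif_screen(v, grp, th)
    mean(d$flagged, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})
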