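# Fixed-parameter EM calibration: starting values, gradient correctness,
# parameter recovery, the fixed-anchor contract, and EM ascent.

test_that("starting thresholds are normal quantiles of cumulative proportions", {
  # uniform frequencies over 3 categories
  vals <- matrix(rep(1:3, each = 30), ncol = 1)
  items <- data.frame(item_id = "u", instrument = "linked", K = 3L)
  init <- initialize_free_items(vals, items)
  expect_equal(init[[1]]$b, qnorm(c(1 / 3, 2 / 3)), tolerance = 1e-9)
  expect_equal(init[[1]]$a, 1.5)
  # symmetric frequencies give symmetric thresholds
  vals2 <- matrix(c(rep(1, 20), rep(2, 60), rep(3, 20)), ncol = 1)
  init2 <- initialize_free_items(vals2, items)
  expect_equal(init2[[1]]$b[1], -init2[[1]]$b[2], tolerance = 1e-9)
  # always strictly increasing, even for skewed margins
  set.seed(9)
  for (rep in 1:10) {
    x <- sample.int(4, 200, replace = TRUE, prob = runif(4)^2 + 0.01)
    ini <- initialize_free_items(matrix(x, ncol = 1),
                                 data.frame(item_id = "x",
                                            instrument = "linked", K = 4L))
    expect_true(all(diff(ini[[1]]$b) > 0))
  }
  expect_error(initialize_free_items(matrix(rep(2L, 50), ncol = 1), items),
               "one category")
})

test_that("the M-step analytic gradient matches finite differences", {
  grid <- make_grid(21, c(-4, 4))
  set.seed(10)
  N <- matrix(rexp(3 * 21), 3, 21)
  par <- c(log(1.7), -0.6, log(1.1))
  g <- pfcrosslink:::mstep_gr(par, N, grid$nodes)
  fd <- vapply(seq_along(par), function(i) {
    h <- 1e-6
    pp <- pm <- par
    pp[i] <- pp[i] + h
    pm[i] <- pm[i] - h
    (pfcrosslink:::mstep_fn(pp, N, grid$nodes) -
       pfcrosslink:::mstep_fn(pm, N, grid$nodes)) / (2 * h)
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-5)
})

test_that("calibration recovers generating parameters at n = 2000", {
  cfg <- synthetic_config(n = c(s = 2000L), theta_mean = -0.8,
                          theta_sd = 0.85)
  banks <- make_item_banks(cfg, 41)
  ds <- simulate_sample(banks, cfg, 42)
  cal <- calibrate_fixed(ds$responses, banks$anchor)
  true_a <- vapply(banks$linked, `[[`, numeric(1), "a")
  est_a <- vapply(cal$free_item_params, `[[`, numeric(1), "a")
  expect_gt(cor(true_a, est_a), 0.9)
  same_K <- vapply(cal$free_item_params, `[[`, integer(1), "K") ==
    vapply(banks$linked, `[[`, integer(1), "K")
  true_b <- unlist(lapply(banks$linked[same_K], `[[`, "b"))
  est_b <- unlist(lapply(cal$free_item_params[same_K], `[[`, "b"))
  expect_lt(mean(abs(true_b - est_b)), 0.15)
  # anchors unchanged, value-identical
  expect_identical(cal$anchor_params, banks$anchor)
  # EM ascent
  expect_true(all(diff(cal$loglik_trace) > -1e-6))
  expect_true(cal$converged)
})

test_that("recalibrating from the solution is idempotent", {
  q <- quick_dataset(seed = 43, n_each = 80)
  cal <- calibrate_fixed(q$dataset$responses, q$banks$anchor, tol = 1e-4)
  cal2 <- calibrate_fixed(q$dataset$responses, q$banks$anchor,
                          init = cal$free_item_params, tol = 1e-4)
  for (j in seq_along(cal$free_item_params)) {
    expect_lt(abs(cal$free_item_params[[j]]$a - cal2$free_item_params[[j]]$a),
              1e-3)
    expect_lt(max(abs(cal$free_item_params[[j]]$b -
                        cal2$free_item_params[[j]]$b)), 1e-3)
  }
})

test_that("the anchor pins the metric of the re-estimated instrument", {
  cfg <- synthetic_config(n = c(s = 1500L), theta_mean = -0.7,
                          theta_sd = 0.8)
  banks <- make_item_banks(cfg, 44)
  ds <- simulate_sample(banks, cfg, 45)
  cal <- calibrate_fixed(ds$responses, banks$anchor)
  sc <- reestimated_link(ds$responses, cal)
  # metric transfer: scoring with the re-estimated parameters reproduces
  # scoring with the generating parameters (both shrink identically, so
  # any difference is a metric shift)
  sc_true <- item_level_link(ds$responses, banks$linked)
  expect_lt(abs(mean(sc$theta) - mean(sc_true$theta)), 0.1)
  expect_gt(cor(sc$theta, sc_true$theta), 0.98)
})

test_that("slope recovery error shrinks with sample size", {
  err_at <- function(n, seed) {
    cfg <- synthetic_config(n = c(s = as.integer(n)), theta_mean = -0.8,
                            theta_sd = 0.85)
    banks <- make_item_banks(cfg, seed)
    ds <- simulate_sample(banks, cfg, seed + 1L)
    cal <- calibrate_fixed(ds$responses, banks$anchor)
    true_a <- vapply(banks$linked, `[[`, numeric(1), "a")
    est_a <- vapply(cal$free_item_params, `[[`, numeric(1), "a")
    mean(abs(true_a - est_a))
  }
  seeds <- c(51, 61, 71)
  e_small <- mean(vapply(seeds, function(s) err_at(500, s), numeric(1)))
  e_large <- mean(vapply(seeds, function(s) err_at(4000, s), numeric(1)))
  expect_lte(e_large, e_small)
})

test_that("sparse categories are collapsed with a recorded mapping", {
  set.seed(12)
  th <- rnorm(300)
  # one linked item whose top category is nearly unreachable
  bank_l <- list(item_parameters("L1", 2, c(-0.5, 6), "linked"),
                 item_parameters("L2", 2, c(-0.8, 0.8), "linked"))
  bank_a <- tiny_bank(6, K = 3, instrument = "anchor", seed = 77)
  vals <- simulate_grm_responses(c(bank_a, bank_l), th, seed = 13)
  items <- data.frame(item_id = colnames(vals),
                      instrument = c(rep("anchor", 6), "linked", "linked"),
                      K = 3L)
  rm <- response_matrix(vals, items)
  expect_warning(cal <- calibrate_fixed(rm, bank_a), "collapsed")
  expect_true("L1" %in% names(cal$category_maps))
  expect_equal(cal$free_item_params[[1]]$K, 2L)
  # scoring with the collapsed parameters still works end to end
  sc <- reestimated_link(rm, cal)
  expect_equal(nrow(sc), 300L)
})
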