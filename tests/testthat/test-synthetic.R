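# Synthetic-data generator: banks, samples, contamination, the exclusion
# screen, and generator faithfulness.

test_that("item banks have the configured shape and are seed-deterministic", {
  cfg <- synthetic_config()
  b1 <- make_item_banks(cfg, 55)
  b2 <- make_item_banks(cfg, 55)
  b3 <- make_item_banks(cfg, 56)
  expect_length(b1$anchor, 20L)
  expect_length(b1$linked, 10L)
  expect_true(all(vapply(b1$anchor, `[[`, integer(1), "K") == 5L))
  expect_true(all(vapply(b1$linked, `[[`, integer(1), "K") == 3L))
  for (it in c(b1$anchor, b1$linked)) expect_true(all(diff(it$b) > 0))
  expect_identical(b1, b2)
  expect_false(identical(b1, b3))
  for (it in b1$anchor) expect_true(it$a >= 1.5 && it$a <= 3.5)
  for (it in b1$linked) expect_true(it$a >= 1.2 && it$a <= 3.0)
})

test_that("simulated samples match the configured latent distributions", {
  cfg <- synthetic_config()
  banks <- make_item_banks(cfg, 57)
  ds <- simulate_sample(banks, cfg, 58)
  expect_length(ds$theta, 619L)
  expect_identical(as.vector(table(ds$subsample)), c(185L, 172L, 262L))
  d2 <- simulate_sample(banks, cfg, 58)
  expect_identical(ds$responses$values, d2$responses$values)
  # cardiology benchmark T mean lands near its configured target
  bench <- observed_benchmark(ds$responses, banks$anchor)
  card <- bench$t_score[ds$subsample == "cardiology"]
  expect_lt(abs(mean(card) - 43.5), 2)
})

test_that("empirical category frequencies match GRM probabilities", {
  bank <- tiny_bank(5, K = 3, seed = 59)
  v <- simulate_grm_responses(bank, rep(0, 50000), seed = 60)
  for (j in seq_along(bank)) {
    emp <- tabulate(v[, j], 3) / 50000
    expect_equal(emp, as.vector(category_probabilities(bank[[j]], 0)),
                 tolerance = 0.01)
  }
})

test_that("contamination reverses and blanks exactly as flagged", {
  q <- quick_dataset(seed = 61, n_each = 100)
  ds <- q$dataset
  # zero fractions: identity
  expect_identical(contaminate(ds, 0, 0, seed = 1), ds)
  dc <- contaminate(ds, reversed_fraction = 43 / 667,
                    missing_fraction = 5 / 667, seed = 62)
  n <- length(ds$theta)
  expect_equal(sum(dc$reversed), round(43 / 667 * n))
  expect_equal(sum(!is.na(dc$missing_instrument)), round(5 / 667 * n))
  # reversed person's linked responses equal K + 1 - original
  linked_cols <- ds$responses$items$instrument == "linked"
  i <- which(dc$reversed)[1]
  expect_identical(unname(dc$responses$values[i, linked_cols]),
                   unname(4L - ds$responses$values[i, linked_cols]))
  # anchor untouched for reversed persons
  expect_identical(dc$responses$values[i, !linked_cols],
                   ds$responses$values[i, !linked_cols])
  # missing person's flagged instrument is wholly NA
  m <- which(!is.na(dc$missing_instrument))[1]
  cols <- ds$responses$items$instrument == dc$missing_instrument[m]
  expect_true(all(is.na(dc$responses$values[m, cols])))
  expect_error(contaminate(ds, 0.7, 0.5, seed = 1), "sum < 1")
})

test_that("a clean dataset passes the screen untouched", {
  q <- quick_dataset(seed = 63, n_each = 80)
  scr <- screen_exclusions(q$dataset, q$banks)
  expect_equal(sum(scr$log$n), 0L)
  expect_equal(length(scr$analytic$theta), length(q$dataset$theta))
})

test_that("the screen detects planted contamination with high sensitivity", {
  sens <- fp <- integer(0)
  for (s in c(64, 65, 66)) {
    cfg <- synthetic_config()
    banks <- make_item_banks(cfg, s)
    ds <- simulate_sample(banks, cfg, s + 1L)
    dc <- contaminate(ds, reversed_fraction = 0.06, missing_fraction = 5 / 667,
                      seed = s + 2L)
    scr <- screen_exclusions(dc, banks)
    # wholly missing instruments always excluded
    miss_ids <- names(dc$missing_instrument)[!is.na(dc$missing_instrument)]
    expect_true(all(miss_ids %in% scr$excluded$person_id))
    rev_ids <- names(dc$reversed)[dc$reversed]
    flagged <- scr$excluded$person_id[scr$excluded$reason == "reversed_coding"]
    sens <- c(sens, sum(rev_ids %in% flagged))
    fp <- c(fp, sum(!(flagged %in% rev_ids)))
  }
  n_rev <- round(0.06 * 619) * 3
  expect_gte(sum(sens) / n_rev, 0.9)
  expect_lte(sum(fp) / (619 * 3 - n_rev), 0.01)
})

test_that("subsample ordering of latent means mirrors the configured clinic profile", {
  cfg <- synthetic_config()
  banks <- make_item_banks(cfg, 67)
  ok <- vapply(1:10, function(s) {
    ds <- simulate_sample(banks, cfg, 300 + s)
    m <- tapply(ds$theta, ds$subsample, mean)
    m["rheumatology"] < m["cardiology"] &&
      m["rheumatology"] < m["psychosomatic"]
  }, logical(1))
  expect_true(all(ok))
})

test_that("anchor scoring recovers the generating traits", {
  cfg <- synthetic_config()
  banks <- make_item_banks(cfg, 68)
  ds <- simulate_sample(banks, cfg, 69)
  bench <- observed_benchmark(ds$responses, banks$anchor)
  expect_gt(cor(ds$theta[bench$person_id], bench$theta), 0.9)
})

test_that("synthetic output files round-trip through the CSV dialects", {
  q <- quick_dataset(seed = 70, n_each = 15)
  dir <- tempfile()
  write_synthetic(q$dataset, q$banks, dir)
  bank_back <- read_item_bank(file.path(dir, "linked_parameters.csv"))
  expect_equal(vapply(bank_back, `[[`, numeric(1), "a"),
               vapply(q$banks$linked, `[[`, numeric(1), "a"),
               tolerance = 1e-12)
  rm_back <- read_responses(file.path(dir, "responses.csv"),
                            items = q$dataset$responses$items)
  expect_identical(rm_back$values, q$dataset$responses$values)
  unlink(dir, recursive = TRUE)
})
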