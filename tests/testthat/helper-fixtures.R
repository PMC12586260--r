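# Small fixture builders shared across the suite. Everything is generated
# in code under explicit seeds; no stored data.

# A tiny deterministic bank of n polytomous items.
tiny_bank <- function(n_items = 3L, K = 3L, instrument = "linked",
                      seed = 42L) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    lapply(seq_len(n_items), function(j) {
      a <- stats::runif(1, 1.2, 2.8)
      ctr <- stats::runif(1, -1, 0.5)
      off <- seq(-0.8, 0.8, length.out = K - 1L)
      item_parameters(sprintf("t%02d", j), a, ctr + off, instrument)
    })
  })
}

# Default-shaped synthetic config with smaller subsamples for speed.
quick_config <- function(n_each = 60L, ...) {
  synthetic_config(n = c(cardiology = n_each, rheumatology = n_each,
                         psychosomatic = n_each), ...)
}

# Clean (uncontaminated) dataset plus its banks.
quick_dataset <- function(seed = 101L, n_each = 60L, ...) {
  cfg <- quick_config(n_each = n_each, ...)
  banks <- make_item_banks(cfg, seed)
  ds <- simulate_sample(banks, cfg, seed + 1L)
  list(cfg = cfg, banks = banks, dataset = ds)
}

# Independent brute-force oracle: bivariate normal CDF by 1-D integration
# of the conditional normal CDF.
pbvnorm_oracle <- function(h, k, rho) {
  if (!is.finite(h)) h <- sign(h) * 37
  if (!is.finite(k)) k <- sign(k) * 37
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((k - rho * x) / sqrt(1 - rho^2)),
    -37, h, rel.tol = 1e-10)$value
}
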