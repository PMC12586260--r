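# Synthetic study-like data: unidimensional GRM responses for a 20-item,
# 5-category anchor instrument and a 10-item, 3-category linked instrument
# over three clinical subsamples, plus the contamination processes (wholly
# missing questionnaires, reversed-coding responders) behind the exclusion
# screen. Provides latent truth for every recovery test.

# Evaluate code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Synthetic-study configuration
#'
#' Defaults are the study conditions: three clinical subsamples
#' (cardiology n = 185, rheumatology n = 172, psychosomatic n = 262) with
#' latent-trait distributions obtained from the per-sample benchmark
#' T-score means/SDs via `theta = (T - 50) / 10`:
#' N(-0.65, 0.78), N(-1.06, 0.90), N(-0.60, 0.86). Contamination rates
#' default to the exclusion screen's observed shares: 43/667 reversed
#' responders and 5/667 wholly missing questionnaires.
#'
#' @param n Named integer vector of subsample sizes.
#' @param theta_mean,theta_sd Latent normal parameters per subsample.
#' @param anchor_items,anchor_categories Anchor instrument shape.
#' @param anchor_a_range,anchor_center_range,anchor_offsets Anchor bank
#'   parameter ranges: slopes uniform on `anchor_a_range`, threshold
#'   centers uniform on `anchor_center_range`, thresholds = center +
#'   `anchor_offsets`.
#' @param linked_items,linked_categories,linked_a_range,linked_center_range,linked_offsets
#'   Same for the linked instrument.
#' @param reversed_fraction,missing_fraction Contamination fractions in
#'   `[0, 1)` with sum < 1.
#' @param seed Optional default seed.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(
    n = c(cardiology = 185L, rheumatology = 172L, psychosomatic = 262L),
    theta_mean = c(-0.65, -1.06, -0.60),
    theta_sd = c(0.78, 0.90, 0.86),
    anchor_items = 20L, anchor_categories = 5L,
    anchor_a_range = c(1.5, 3.5), anchor_center_range = c(-2.5, 1.0),
    anchor_offsets = c(-1.5, -0.5, 0.5, 1.5),
    linked_items = 10L, linked_categories = 3L,
    linked_a_range = c(1.2, 3.0), linked_center_range = c(-2.5, 0.5),
    linked_offsets = c(-0.8, 0.8),
    reversed_fraction = 43 / 667, missing_fraction = 5 / 667,
    seed = NULL) {
  # YAML configs deliver sequences/maps as lists; flatten them
  n <- unlist(n); theta_mean <- unlist(theta_mean); theta_sd <- unlist(theta_sd)
  anchor_a_range <- unlist(anchor_a_range)
  anchor_center_range <- unlist(anchor_center_range)
  anchor_offsets <- unlist(anchor_offsets)
  linked_a_range <- unlist(linked_a_range)
  linked_center_range <- unlist(linked_center_range)
  linked_offsets <- unlist(linked_offsets)
  if (length(n) != length(theta_mean) || length(n) != length(theta_sd))
    stop("n, theta_mean, theta_sd must align", call. = FALSE)
  if (any(n < 1L)) stop("subsample sizes must be >= 1", call. = FALSE)
  if (any(theta_sd <= 0)) stop("theta_sd must be positive", call. = FALSE)
  if (is.null(names(n))) names(n) <- paste0("sample", seq_along(n))
  stopifnot(length(anchor_offsets) == anchor_categories - 1L,
            length(linked_offsets) == linked_categories - 1L)
  for (r in list(anchor_a_range, anchor_center_range, linked_a_range,
                 linked_center_range))
    if (length(r) != 2L || r[1] > r[2]) stop("invalid range", call. = FALSE)
  if (reversed_fraction < 0 || reversed_fraction >= 1 ||
      missing_fraction < 0 || missing_fraction >= 1 ||
      reversed_fraction + missing_fraction >= 1)
    stop("contamination fractions must lie in [0, 1) with sum < 1",
         call. = FALSE)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Draw the anchor and linked item banks
#'
#' Anchor: `anchor_items` items with `anchor_categories` ordered
#' categories, slopes uniform on the configured range, thresholds = a
#' uniform center plus fixed offsets (ordered by construction). Same for
#' the linked bank. Deterministic given the seed.
#'
#' @param config A [synthetic_config].
#' @param seed Integer seed (falls back to `config$seed`).
#' @return List `anchor`, `linked` of [item_parameters] lists.
#' @export
make_item_banks <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    draw <- function(n_items, a_range, c_range, offsets, prefix, instr) {
      a <- stats::runif(n_items, a_range[1], a_range[2])
      ctr <- stats::runif(n_items, c_range[1], c_range[2])
      lapply(seq_len(n_items), function(j)
        item_parameters(sprintf("%s%02d", prefix, j), a[j],
                        ctr[j] + offsets, instr))
    }
    list(anchor = draw(config$anchor_items, config$anchor_a_range,
                       config$anchor_center_range, config$anchor_offsets,
                       "anchor", "anchor"),
         linked = draw(config$linked_items, config$linked_a_range,
                       config$linked_center_range, config$linked_offsets,
                       "linked", "linked"))
  })
}

#' Simulate GRM responses for given latent-trait values
#'
#' One column per bank item; categories drawn from the model's category
#' probabilities at each person's theta.
#'
#' @param bank List of [item_parameters].
#' @param theta Numeric vector of latent traits.
#' @param seed Optional seed.
#' @return Integer matrix `length(theta) x length(bank)` with the bank's
#'   item ids as column names.
#' @export
simulate_grm_responses <- function(bank, theta, seed = NULL) {
  validate_bank(bank)
  with_seed(seed, {
    n <- length(theta)
    out <- matrix(NA_integer_, n, length(bank),
                  dimnames = list(NULL, bank_ids(bank)))
    for (j in seq_along(bank)) {
      it <- bank[[j]]
      cum <- stats::plogis(it$a * outer(theta, it$b, "-"))  # P(X >= k+1)
      u <- stats::runif(n)
      out[, j] <- 1L + as.integer(rowSums(u < cum))
    }
    out
  })
}

#' Simulate a full synthetic study sample
#'
#' Draws each subsample's latent traits from its configured normal, then
#' responses for both instruments from the GRM. No contamination is
#' applied here (see [contaminate]).
#'
#' @param banks Result of [make_item_banks].
#' @param config A [synthetic_config].
#' @param seed Integer seed.
#' @return An object of class `synthetic_dataset`: list with `responses`
#'   (a [response_matrix] over both instruments), `theta` (latent truth),
#'   `subsample` (factor), `reversed` and `missing_instrument`
#'   contamination flags (all clean here).
#' @export
simulate_sample <- function(banks, config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    sub <- factor(rep(names(config$n), config$n), levels = names(config$n))
    n <- length(sub)
    theta <- stats::rnorm(n, config$theta_mean[as.integer(sub)],
                          config$theta_sd[as.integer(sub)])
    bank_all <- c(banks$anchor, banks$linked)
    vals <- simulate_grm_responses(bank_all, theta)
    items <- data.frame(item_id = bank_ids(bank_all),
                        instrument = vapply(bank_all, `[[`, character(1),
                                            "instrument"),
                        K = bank_K(bank_all), stringsAsFactors = FALSE)
    ids <- sprintf("P%04d", seq_len(n))
    structure(list(responses = response_matrix(vals, items, ids),
                   theta = stats::setNames(theta, ids),
                   subsample = sub,
                   reversed = stats::setNames(rep(FALSE, n), ids),
                   missing_instrument = stats::setNames(
                     rep(NA_character_, n), ids)),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic dataset: %d persons (%s), %d reversed, %d missing-instrument>\n",
              length(x$theta),
              paste(sprintf("%s=%d", levels(x$subsample),
                            tabulate(x$subsample)), collapse = ", "),
              sum(x$reversed), sum(!is.na(x$missing_instrument))))
  invisible(x)
}

#' Contaminate a synthetic dataset
#'
#' Emulates the exclusion screen's two contamination processes: a random
#' subset of persons has the linked instrument's categories reversed
#' (`k -> K + 1 - k`, reversed-coding bias), and a disjoint subset has one
#' randomly chosen instrument set wholly missing. Truth flags are
#' recorded. Counts are `round(fraction * n)`, so the defaults reproduce
#' the screen's expected 43 and 5 on n = 667.
#'
#' @param dataset A [simulate_sample] dataset.
#' @param reversed_fraction,missing_fraction Fractions in `[0, 1)` with
#'   sum < 1 (defaults from the dataset's config are not retained; pass
#'   explicitly or use [synthetic_config] defaults).
#' @param seed Integer seed.
#' @return The contaminated `synthetic_dataset`.
#' @export
contaminate <- function(dataset, reversed_fraction = 43 / 667,
                        missing_fraction = 5 / 667, seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (reversed_fraction < 0 || missing_fraction < 0 ||
      reversed_fraction + missing_fraction >= 1)
    stop("contamination fractions must lie in [0, 1) with sum < 1",
         call. = FALSE)
  n <- length(dataset$theta)
  n_rev <- round(reversed_fraction * n)
  n_mis <- round(missing_fraction * n)
  if (n_rev + n_mis == 0L) return(dataset)
  with_seed(seed, {
    pick <- sample.int(n, n_rev + n_mis)
    rev_i <- pick[seq_len(n_rev)]
    mis_i <- pick[setdiff(seq_len(n_rev + n_mis), seq_len(n_rev))]
    vals <- dataset$responses$values
    items <- dataset$responses$items
    linked_cols <- which(items$instrument == "linked")
    for (j in linked_cols) {
      K <- items$K[j]
      vals[rev_i, j] <- K + 1L - vals[rev_i, j]
    }
    if (length(mis_i)) {
      which_instr <- sample(c("anchor", "linked"), length(mis_i),
                            replace = TRUE)
      for (k in seq_along(mis_i)) {
        cols <- which(items$instrument == which_instr[k])
        vals[mis_i[k], cols] <- NA_integer_
      }
      dataset$missing_instrument[mis_i] <- which_instr
    }
    dataset$responses$values <- vals
    dataset$reversed[rev_i] <- TRUE
    dataset
  })
}

#' Exclusion screen: wholly missing instruments and reversed coding
#'
#' Reproduces the analytic-sample screen: persons with one instrument
#' wholly missing are dropped; remaining persons are flagged as likely
#' reversed-coding responders when either (a) their standardized
#' within-subsample mean scores on the two instruments have opposite signs
#' and differ by more than `z_gap` SDs, or (b) the linked instrument's
#' responses are more likely under the reversed key than the normal key by
#' more than `nats` nats, evaluated at the person's anchor-based EAP
#' theta. Both thresholds are exposed; the heuristic is validated only
#' against planted synthetic truth.
#'
#' @param dataset A `synthetic_dataset`.
#' @param banks Item banks used for the likelihood criterion.
#' @param grid Quadrature grid.
#' @param z_gap Z-score-gap threshold (criterion a).
#' @param nats Log-likelihood margin in nats (criterion b).
#'
#' @return List with `analytic` (the screened `synthetic_dataset`),
#'   `log` (data frame of exclusion counts by reason), `excluded`
#'   (data frame `person_id, reason`).
#' @export
screen_exclusions <- function(dataset, banks, grid = make_grid(),
                              z_gap = 3, nats = 5) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  vals <- dataset$responses$values
  items <- dataset$responses$items
  a_cols <- which(items$instrument == "anchor")
  l_cols <- which(items$instrument == "linked")
  ids <- dataset$responses$person_ids

  miss <- rowSums(!is.na(vals[, a_cols, drop = FALSE])) == 0L |
    rowSums(!is.na(vals[, l_cols, drop = FALSE])) == 0L

  # reversed-coding flags among persons with both instruments present
  cand <- which(!miss)
  flag_rev <- rep(FALSE, length(ids))
  if (length(cand)) {
    # (a) z-gap rule on within-subsample standardized mean item scores
    ms_a <- rowMeans(vals[cand, a_cols, drop = FALSE], na.rm = TRUE)
    ms_l <- rowMeans(vals[cand, l_cols, drop = FALSE], na.rm = TRUE)
    z_a <- z_l <- rep(NA_real_, length(cand))
    for (g in levels(dataset$subsample)) {
      i <- dataset$subsample[cand] == g
      if (sum(i) >= 2L) {
        z_a[i] <- (ms_a[i] - mean(ms_a[i])) / stats::sd(ms_a[i])
        z_l[i] <- (ms_l[i] - mean(ms_l[i])) / stats::sd(ms_l[i])
      }
    }
    rule_a <- !is.na(z_a) & !is.na(z_l) & (z_a * z_l < 0) &
      (abs(z_a - z_l) > z_gap)

    # (b) likelihood margin at the anchor-based EAP theta
    e <- eap_from_loglik(
      loglik_matrix(vals[cand, a_cols, drop = FALSE][, bank_ids(banks$anchor),
                                                     drop = FALSE],
                    banks$anchor, grid), grid)
    lv <- vals[cand, l_cols, drop = FALSE][, bank_ids(banks$linked),
                                           drop = FALSE]
    Kl <- bank_K(banks$linked)
    rv <- lv
    for (j in seq_along(Kl)) rv[, j] <- Kl[j] + 1L - lv[, j]
    rule_b <- rep(FALSE, length(cand))
    for (p in seq_along(cand)) {
      ll_n <- pattern_log_likelihood(lv[p, ], banks$linked, e$theta[p])
      ll_r <- pattern_log_likelihood(rv[p, ], banks$linked, e$theta[p])
      rule_b[p] <- (ll_r - ll_n) > nats
    }
    flag_rev[cand] <- rule_a | rule_b
  }

  reason <- rep(NA_character_, length(ids))
  reason[miss] <- "missing_instrument"
  reason[!miss & flag_rev] <- "reversed_coding"
  keep <- is.na(reason)

  analytic <- dataset
  analytic$responses$values <- vals[keep, , drop = FALSE]
  analytic$responses$person_ids <- ids[keep]
  analytic$theta <- dataset$theta[keep]
  analytic$subsample <- droplevels(dataset$subsample[keep])
  analytic$subsample <- factor(analytic$subsample,
                               levels = levels(dataset$subsample))
  analytic$reversed <- dataset$reversed[keep]
  analytic$missing_instrument <- dataset$missing_instrument[keep]

  log <- data.frame(
    reason = c("missing_instrument", "reversed_coding"),
    n = c(sum(reason == "missing_instrument", na.rm = TRUE),
          sum(reason == "reversed_coding", na.rm = TRUE)))
  list(analytic = analytic, log = log,
       excluded = data.frame(person_id = ids[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Write a synthetic dataset's truth and responses to CSV
#'
#' Emits the response CSV, a truth CSV (`person_id, subsample, theta_true,
#' reversed, missing_instrument`) and the generating parameter CSVs.
#'
#' @param dataset A `synthetic_dataset`.
#' @param banks The generating banks.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, banks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_responses(dataset$responses, file.path(dir, "responses.csv"))
  truth <- data.frame(person_id = dataset$responses$person_ids,
                      subsample = as.character(dataset$subsample),
                      theta_true = unname(dataset$theta),
                      reversed = dataset$reversed,
                      missing_instrument = dataset$missing_instrument,
                      stringsAsFactors = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   na = "")
  write_item_bank(banks$anchor, file.path(dir, "anchor_parameters.csv"))
  write_item_bank(banks$linked, file.path(dir, "linked_parameters.csv"))
  invisible(dir)
}
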