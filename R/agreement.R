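# Agreement between observed (benchmark) and linked T-scores: Pearson r,
# mean difference, MAE/RMSE with bootstrap percentile CIs, paired
# standardized mean differences, and Bland-Altman limits of agreement,
# overall and per clinical subsample.

#' Paired standardized mean difference from summary statistics
#'
#' `SMD = mean_diff / sqrt((sd_a^2 + sd_b^2) / 2)`. The denominator is the
#' pooled SD of the two score sets (not the SD of the differences): this is
#' the convention under which the published per-sample SMDs reconcile with
#' the published mean differences and score SDs.
#'
#' @param mean_diff Mean of paired differences (a - b).
#' @param sd_a,sd_b SDs of the two score vectors (both positive).
#' @return The standardized mean difference.
#' @examples
#' smd_from_summary(-0.11, 8.66, 10.30)  # about -0.01
#' @export
smd_from_summary <- function(mean_diff, sd_a, sd_b) {
  if (!is.finite(mean_diff)) stop("mean_diff must be finite", call. = FALSE)
  if (!is.finite(sd_a) || !is.finite(sd_b) || sd_a <= 0 || sd_b <= 0)
    stop("sd_a and sd_b must be positive", call. = FALSE)
  mean_diff / sqrt((sd_a^2 + sd_b^2) / 2)
}

# Point statistics of one paired comparison; diff = observed - linked.
agreement_stats <- function(observed, linked) {
  n <- length(observed)
  d <- observed - linked
  md <- mean(d)
  sdd <- stats::sd(d)
  mae <- mean(abs(d))
  rmse <- sqrt(mean(d^2))
  r <- if (stats::sd(observed) == 0 || stats::sd(linked) == 0) NA_real_
       else stats::cor(observed, linked)
  smd <- if (stats::sd(observed) > 0 && stats::sd(linked) > 0)
    smd_from_summary(md, stats::sd(observed), stats::sd(linked))
  else NA_real_
  list(n = n, pearson_r = r, mean_diff = md, sd_diff = sdd, mae = mae,
       rmse = rmse, smd = smd,
       loa = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
       mean_obs = mean(observed), sd_obs = stats::sd(observed),
       mean_linked = mean(linked), sd_linked = stats::sd(linked),
       zero_variance = stats::sd(observed) == 0 || stats::sd(linked) == 0)
}

#' Bootstrap percentile confidence interval for an agreement statistic
#'
#' Person-level resampling with replacement; percentile 2.5/97.5 bounds.
#' Deterministic for a given seed.
#'
#' @param observed,linked Paired score vectors (length >= 3).
#' @param statistic One of `"mae"`, `"rmse"`, `"smd"`.
#' @param B Number of bootstrap resamples (>= 200).
#' @param seed Integer seed (mandatory: all randomness is explicit).
#' @param conf Confidence level.
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(observed, linked, statistic = c("mae", "rmse", "smd"),
                         B = 1000L, seed, conf = 0.95) {
  statistic <- match.arg(statistic)
  ci <- bootstrap_cis(observed, linked, B = B, seed = seed, conf = conf)
  ci[[statistic]]
}

# All three statistics over one shared resampling stream.
bootstrap_cis <- function(observed, linked, B = 1000L, seed, conf = 0.95) {
  if (length(observed) != length(linked) || length(observed) < 3L)
    stop("need paired vectors of length >= 3", call. = FALSE)
  if (B < 200L) stop("B must be >= 200", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("bootstrap seed is mandatory", call. = FALSE)
  n <- length(observed)
  stat <- matrix(NA_real_, B, 3L, dimnames = list(NULL,
                                                  c("mae", "rmse", "smd")))
  with_seed(seed, {
    for (b in seq_len(B)) {
      i <- sample.int(n, n, replace = TRUE)
      d <- observed[i] - linked[i]
      stat[b, 1L] <- mean(abs(d))
      stat[b, 2L] <- sqrt(mean(d^2))
      so <- stats::sd(observed[i]); sl <- stats::sd(linked[i])
      stat[b, 3L] <- if (so > 0 && sl > 0)
        mean(d) / sqrt((so^2 + sl^2) / 2) else NA_real_
    }
  })
  a <- (1 - conf) / 2
  lapply(as.data.frame(stat), function(s)
    unname(stats::quantile(s, c(a, 1 - a), na.rm = TRUE)))
}

#' Agreement report between observed and linked T-scores
#'
#' Pearson correlation, mean difference (observed - linked) with its SD,
#' MAE and RMSE with bootstrap percentile CIs, paired pooled-SD SMD with
#' CI, and Bland-Altman limits of agreement -- overall and within each
#' subsample.
#'
#' @param observed,linked Paired T-score vectors (length >= 3, matched by
#'   person).
#' @param subsample Optional per-person subsample labels.
#' @param B Bootstrap resamples (0 disables CIs).
#' @param seed Bootstrap seed (required when `B > 0`).
#' @param conf Confidence level for the CIs.
#'
#' @return An object of class `agreement_report`: list with `overall` and
#'   `by_subsample` (named list), each holding n, pearson_r, mean_diff,
#'   sd_diff, mae, rmse, smd, loa, ci_mae, ci_rmse, ci_smd and the summary
#'   means/SDs of both score sets.
#' @export
score_agreement <- function(observed, linked, subsample = NULL, B = 1000L,
                            seed = NULL, conf = 0.95) {
  if (length(observed) != length(linked))
    stop("observed and linked must be paired", call. = FALSE)
  if (length(observed) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(observed) || anyNA(linked))
    stop("scores must not contain NA", call. = FALSE)
  one <- function(o, l, sd) {
    s <- agreement_stats(o, l)
    if (B > 0L) {
      ci <- bootstrap_cis(o, l, B = B, seed = sd, conf = conf)
      s$ci_mae <- ci$mae; s$ci_rmse <- ci$rmse; s$ci_smd <- ci$smd
    } else {
      s$ci_mae <- s$ci_rmse <- s$ci_smd <- c(NA_real_, NA_real_)
    }
    s
  }
  if (B > 0L && (is.null(seed)))
    stop("seed required when B > 0", call. = FALSE)
  out <- list(overall = one(observed, linked, seed))
  by <- list()
  if (!is.null(subsample)) {
    subsample <- as.character(subsample)
    for (g in unique(subsample)) {
      i <- subsample == g
      if (sum(i) >= 3L)
        by[[g]] <- one(observed[i], linked[i],
                       if (is.null(seed)) NULL else seed + match(g, unique(subsample)))
    }
  }
  out$by_subsample <- by
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<agreement: n=%d, r=%.2f, MD=%.2f (SD %.2f), MAE=%.2f, RMSE=%.2f, SMD=%.2f>\n",
              o$n, o$pearson_r, o$mean_diff, o$sd_diff, o$mae, o$rmse,
              o$smd))
  invisible(x)
}

#' Bland-Altman decomposition of paired T-scores
#'
#' Per-person (average, difference) records plus, per subsample, the mean
#' difference, 95% limits of agreement `MD +/- 1.96 SD`, and the
#' least-squares trend of difference on average (slope, intercept, 95%
#' band) -- the per-sample colored lines of the usual plot. Subsamples with
#' fewer than 3 persons get no trend (flagged).
#'
#' @inheritParams score_agreement
#' @param person_ids Optional person identifiers.
#' @return List with `records` (data frame `person_id, subsample, average,
#'   difference`) and `summary` (per-subsample data frame with md,
#'   loa_lower, loa_upper, trend_intercept, trend_slope, slope CI and
#'   `trend_omitted`).
#' @export
bland_altman <- function(observed, linked, subsample = NULL,
                         person_ids = NULL) {
  if (length(observed) != length(linked))
    stop("observed and linked must be paired", call. = FALSE)
  n <- length(observed)
  if (is.null(person_ids)) person_ids <- sprintf("P%04d", seq_len(n))
  if (is.null(subsample)) subsample <- rep("all", n)
  rec <- data.frame(person_id = person_ids,
                    subsample = as.character(subsample),
                    average = (observed + linked) / 2,
                    difference = observed - linked,
                    stringsAsFactors = FALSE)
  summ <- lapply(split(rec, rec$subsample), function(d) {
    md <- mean(d$difference)
    sdd <- stats::sd(d$difference)
    base <- data.frame(subsample = d$subsample[1L], n = nrow(d), md = md,
                       loa_lower = md - 1.96 * sdd,
                       loa_upper = md + 1.96 * sdd)
    if (nrow(d) < 3L) {
      base$trend_intercept <- base$trend_slope <- base$slope_lo <-
        base$slope_hi <- NA_real_
      base$trend_omitted <- TRUE
    } else {
      fit <- stats::lm(difference ~ average, data = d)
      ci <- stats::confint(fit)["average", ]
      base$trend_intercept <- unname(stats::coef(fit)[1L])
      base$trend_slope <- unname(stats::coef(fit)[2L])
      base$slope_lo <- ci[1L]; base$slope_hi <- ci[2L]
      base$trend_omitted <- FALSE
    }
    base
  })
  list(records = rec, summary = do.call(rbind, c(summ,
                                                 make.row.names = FALSE)))
}

#' Round half away from zero
#'
#' Reporting convention for the output tables (2 decimals, half away from
#' zero), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
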