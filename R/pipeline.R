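# Config-driven orchestration of the full validation flow: screen ->
# assumption checks -> three linking approaches -> agreement evaluation,
# with table/JSON outputs shaped like the study's reporting tables.

#' Default run configuration
#'
#' One place for every default: grid spec, bootstrap spec, DIF spec,
#' calibration settings, benchmark flags. Override any entry through the
#' `config` argument of [run_validation] (or a YAML file with the same
#' keys, read by [read_run_config]).
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synthetic = list(),           # overrides for synthetic_config()
    grid = list(n_nodes = 49L, bounds = c(-6, 6), prior_mean = 0,
                prior_sd = 1),
    bootstrap = list(B = 1000L),
    dif = list(threshold = 0.03, group = "subsample"),
    calibration = list(tol = 1e-4, max_cycles = 500L, min_cat_count = 5L),
    screen = list(z_gap = 3, nats = 5),
    check_assumptions = TRUE,
    n_group_factors = 4L,
    rounding = 2L,
    out_dir = NULL)
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys mirror [default_config].
#' @return The configuration list (unvalidated; merged inside
#'   [run_validation]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  yaml::read_yaml(path)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Run the full linking-validation pipeline
#'
#' Executes, in order: synthetic data generation (banks, sample,
#' contamination), the exclusion screen, assumption checks
#' (dimensionality and DIF), benchmark scoring, the three linking
#' approaches (item-level, crosswalk, fixed-parameter re-estimation), and
#' agreement evaluation overall and per subsample. Deterministic: the
#' whole run is a pure function of the configuration, with all
#' stage seeds derived from `config$seed`.
#'
#' @param config List of overrides of [default_config], or a path to a
#'   YAML file of them.
#'
#' @return An object of class `validation_report`: list with elements
#'   `config`, `banks`, `screen_log`, `bookkeeping`, `assumptions`,
#'   `scores` (per method), `agreement` (per method), `tables` (data
#'   frames `table3`, `table4`, `table5`), `bland_altman`, `calibration`.
#' @export
run_validation <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(default_config(), config)
  seed <- as.integer(cfg$seed)
  grid <- make_grid(cfg$grid$n_nodes, unlist(cfg$grid$bounds),
                    cfg$grid$prior_mean, cfg$grid$prior_sd)

  # --- stage 1: data -------------------------------------------------------
  scfg <- do.call(synthetic_config, cfg$synthetic)
  banks <- make_item_banks(scfg, seed = seed)
  dataset <- simulate_sample(banks, scfg, seed = seed + 1L)
  dataset <- contaminate(dataset, scfg$reversed_fraction,
                         scfg$missing_fraction, seed = seed + 2L)
  n_initial <- length(dataset$theta)

  # --- stage 2: exclusion screen ------------------------------------------
  scr <- screen_exclusions(dataset, banks, grid, cfg$screen$z_gap,
                           cfg$screen$nats)
  analytic <- scr$analytic
  rm_a <- analytic$responses
  n_analytic <- length(analytic$theta)
  book <- list(n_initial = n_initial,
               n_excluded = n_initial - n_analytic,
               n_analytic = n_analytic,
               exclusions = scr$log,
               subsample_n = tabulate(analytic$subsample,
                                      nlevels(analytic$subsample)),
               subsample_share = subsample_shares(
                 tabulate(analytic$subsample, nlevels(analytic$subsample))))
  names(book$subsample_n) <- names(book$subsample_share) <-
    levels(analytic$subsample)
  stopifnot(book$n_initial - sum(book$exclusions$n) == book$n_analytic)

  # --- stage 3: assumption checks -----------------------------------------
  assumptions <- NULL
  if (isTRUE(cfg$check_assumptions)) {
    dim_rep <- dimensionality_report(rm_a$values, cfg$n_group_factors)
    pooled_bank <- c(banks$anchor, banks$linked)
    trait <- eap_from_loglik(
      loglik_matrix(rm_a$values[, bank_ids(pooled_bank), drop = FALSE],
                    pooled_bank, grid), grid)$theta
    dif <- dif_screen(rm_a$values, analytic$subsample, trait,
                      cfg$dif$threshold)
    assumptions <- list(dimensionality = dim_rep, dif = dif)
  }

  # --- stage 4: benchmark and the three linking approaches -----------------
  bench <- observed_benchmark(rm_a, banks$anchor, grid)
  m1 <- item_level_link(rm_a, banks$linked, grid)
  xwalk <- build_crosswalk(banks$linked, grid, bank_id = "linked-original")
  m2 <- apply_crosswalk(raw_summed_scores(rm_a, banks$linked), xwalk)
  calib <- calibrate_fixed(rm_a, banks$anchor, grid = grid,
                           tol = cfg$calibration$tol,
                           max_cycles = cfg$calibration$max_cycles,
                           min_cat_count = cfg$calibration$min_cat_count)
  m3 <- reestimated_link(rm_a, calib, grid)
  methods <- list("IRT re-estimation" = m3,
                  "item-level linking" = m1,
                  "cross-walk table" = m2)

  # --- stage 5: agreement --------------------------------------------------
  sub_by_id <- stats::setNames(as.character(analytic$subsample),
                               rm_a$person_ids)
  agreement <- list()
  ba_records <- NULL
  ba_summaries <- list()
  for (meth in names(methods)) {
    sc <- methods[[meth]]
    common <- intersect(bench$person_id, sc$person_id)
    o <- bench$t_score[match(common, bench$person_id)]
    l <- sc$t_score[match(common, sc$person_id)]
    lab <- sub_by_id[common]
    agreement[[meth]] <- score_agreement(o, l, lab, B = cfg$bootstrap$B,
                                         seed = seed + 100L)
    ba <- bland_altman(o, l, lab, person_ids = common)
    ba$records$method <- meth
    ba$summary$method <- meth
    ba_records <- rbind(ba_records, ba$records)
    ba_summaries[[meth]] <- ba$summary
  }

  tables <- build_tables(bench, methods, agreement, sub_by_id,
                         levels(analytic$subsample))

  report <- structure(
    list(config = cfg, banks = banks, screen_log = scr$log,
         excluded = scr$excluded, bookkeeping = book,
         assumptions = assumptions, benchmark = bench, scores = methods,
         crosswalk_table = xwalk, calibration = calib,
         agreement = agreement, tables = tables,
         bland_altman = list(records = ba_records,
                             summary = do.call(rbind, c(ba_summaries,
                                                        make.row.names = FALSE)))),
    class = "validation_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Percentage shares of subsample sizes
#'
#' @param n Integer vector of subsample sizes.
#' @param digits Decimal places (half-away-from-zero).
#' @return Percent shares summing to ~100.
#' @examples
#' subsample_shares(c(185, 172, 262))  # 29.89 27.79 42.33
#' @export
subsample_shares <- function(n, digits = 2L) {
  round_half_up(100 * n / sum(n), digits)
}

# Report tables shaped like the study's Tables 3-5.
build_tables <- function(bench, methods, agreement, sub_by_id, sub_levels) {
  samples <- c("analytic", sub_levels)
  t3 <- t5 <- NULL
  t4 <- NULL
  # table 4: means/SDs of each score set, benchmark first
  mk4 <- function(label, sc) {
    rows <- lapply(samples, function(s) {
      i <- if (s == "analytic") rep(TRUE, nrow(sc))
           else sub_by_id[sc$person_id] == s
      data.frame(method = label, sample = s, n = sum(i),
                 mean = mean(sc$t_score[i]), sd = stats::sd(sc$t_score[i]))
    })
    do.call(rbind, rows)
  }
  t4 <- rbind(mk4("observed benchmark", bench),
              do.call(rbind, lapply(names(methods),
                                    function(m) mk4(m, methods[[m]]))))
  for (meth in names(methods)) {
    agr <- agreement[[meth]]
    all_reports <- c(list(analytic = agr$overall), agr$by_subsample)
    for (s in names(all_reports)) {
      a <- all_reports[[s]]
      t3 <- rbind(t3, data.frame(
        sample = s, method = meth, n = a$n, r = a$pearson_r,
        md = a$mean_diff, sd = a$sd_diff))
      t5 <- rbind(t5, data.frame(
        sample = s, method = meth, n = a$n,
        mae = a$mae, mae_lo = a$ci_mae[1], mae_hi = a$ci_mae[2],
        rmse = a$rmse, rmse_lo = a$ci_rmse[1], rmse_hi = a$ci_rmse[2],
        smd = a$smd, smd_lo = a$ci_smd[1], smd_hi = a$ci_smd[2]))
    }
  }
  list(table3 = t3, table4 = t4, table5 = t5)
}

#' Write a validation report's files
#'
#' Emits `table2.json` (assumption checks in statistic / criterion /
#' result / pass layout), `table3.csv`, `table4.csv`, `table5.csv`,
#' `bland_altman.csv` and `run_log.json`.
#'
#' @param report A [run_validation] report.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rnd <- function(d) {
    num <- vapply(d, is.numeric, logical(1)) &
      !(names(d) %in% c("n"))
    d[num] <- lapply(d[num], round_half_up, report$config$rounding)
    d
  }
  utils::write.csv(rnd(report$tables$table3),
                   file.path(dir, "table3.csv"), row.names = FALSE)
  utils::write.csv(rnd(report$tables$table4),
                   file.path(dir, "table4.csv"), row.names = FALSE)
  utils::write.csv(rnd(report$tables$table5),
                   file.path(dir, "table5.csv"), row.names = FALSE)
  utils::write.csv(report$bland_altman$records,
                   file.path(dir, "bland_altman.csv"), row.names = FALSE)
  if (!is.null(report$assumptions)) {
    f <- report$assumptions$dimensionality$one_factor
    b <- report$assumptions$dimensionality$bifactor
    t2 <- list(
      list(statistic = "CFI", criterion = "> 0.95", result = f$fit$cfi,
           pass = f$benchmark_flags$cfi),
      list(statistic = "TLI", criterion = "> 0.95", result = f$fit$tli,
           pass = f$benchmark_flags$tli),
      list(statistic = "RMSEA", criterion = "< 0.06",
           result = f$fit$rmsea, pass = f$benchmark_flags$rmsea),
      list(statistic = "SRMR", criterion = "< 0.08",
           result = f$fit$srmr, pass = f$benchmark_flags$srmr),
      list(statistic = "ECV", criterion = "> 0.60", result = b$ecv,
           pass = b$benchmark_flags$ecv),
      list(statistic = "OmegaH", criterion = "> 0.80", result = b$omega_h,
           pass = b$benchmark_flags$omega_h))
    jsonlite::write_json(t2, file.path(dir, "table2.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(report$assumptions$dif, file.path(dir, "dif.csv"),
                     row.names = FALSE)
  }
  log <- list(seed = report$config$seed,
              bookkeeping = report$bookkeeping,
              calibration = list(converged = report$calibration$converged,
                                 n_cycles = report$calibration$n_cycles),
              checks = derive_summary_checks(report))
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Internal-consistency flags of a validation report
#'
#' Verifies, on the report's own numbers: the RMSE/MD/SD identity
#' (`rmse^2 = md^2 + sd^2 (n-1)/n`), recomputation of every SMD from the
#' summary statistics of table 4 and the MD of table 3, crosswalk T-score
#' monotonicity, and bookkeeping (exclusions reconcile and subsample
#' shares sum to 100).
#'
#' @param report A [run_validation] report.
#' @return Named list of logical flags, all `TRUE` for a sound report.
#' @export
derive_summary_checks <- function(report) {
  t3 <- report$tables$table3
  t4 <- report$tables$table4
  t5 <- report$tables$table5
  rmse_ok <- all(abs(t5$rmse^2 -
                       (t3$md^2 + t3$sd^2 * (t3$n - 1) / t3$n)) < 1e-9)
  smd_ok <- TRUE
  for (i in seq_len(nrow(t5))) {
    sd_o <- t4$sd[t4$method == "observed benchmark" &
                    t4$sample == t5$sample[i]]
    sd_l <- t4$sd[t4$method == t5$method[i] & t4$sample == t5$sample[i]]
    md <- t3$md[t3$method == t5$method[i] & t3$sample == t5$sample[i]]
    smd_ok <- smd_ok &&
      abs(smd_from_summary(md, sd_o, sd_l) - t5$smd[i]) < 1e-9
  }
  xw_ok <- !is.unsorted(report$crosswalk_table$t_score)
  book <- report$bookkeeping
  book_ok <- (book$n_initial - book$n_excluded == book$n_analytic) &&
    abs(sum(book$subsample_share) - 100) < 0.05 &&
    sum(book$subsample_n) == book$n_analytic
  list(rmse_identity = rmse_ok, smd_recomputation = smd_ok,
       crosswalk_monotone = xw_ok, bookkeeping = book_ok)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation report: n=%d analytic (of %d), 3 linking methods>\n",
              x$bookkeeping$n_analytic, x$bookkeeping$n_initial))
  t3 <- x$tables$table3
  an <- t3[t3$sample == "analytic", ]
  for (i in seq_len(nrow(an)))
    cat(sprintf("  %-20s r=%.2f MD=%5.2f (SD %.2f)\n", an$method[i],
                an$r[i], an$md[i], an$sd[i]))
  invisible(x)
}
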