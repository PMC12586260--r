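# EAP response-pattern scoring against fixed item parameters: the observed
# 20-item benchmark T-scores and linking approach 1 (item-level linking).

# n x G log-likelihood matrix; missing responses contribute 0.
loglik_matrix <- function(values, bank, grid) {
  n <- nrow(values)
  G <- length(grid$nodes)
  L <- matrix(0, n, G)
  for (j in seq_along(bank)) {
    lp <- item_log_probs(bank[[j]], grid$nodes)  # K x G
    x <- values[, j]
    obs <- which(!is.na(x))
    if (length(obs))
      L[obs, ] <- L[obs, ] + lp[x[obs], , drop = FALSE]
  }
  L
}

# EAP mean/SD per row of a log-likelihood matrix.
eap_from_loglik <- function(L, grid) {
  lw <- sweep(L, 2, log(grid$weights), "+")
  m <- apply(lw, 1, max)
  p <- exp(lw - m)
  den <- rowSums(p)
  th <- as.vector(p %*% grid$nodes) / den
  v <- as.vector(p %*% grid$nodes^2) / den - th^2
  list(theta = th, se = sqrt(pmax(v, 0)),
       log_marginal = m + log(den))
}

#' EAP score for a single response pattern
#'
#' Posterior mean and SD of the latent trait given one response pattern,
#' computed by quadrature against the grid's normal prior. Item parameters
#' are treated as known constants. An all-missing pattern returns the prior
#' mean/SD with `all_missing = TRUE`.
#'
#' @param pattern Integer vector of categories (1-based, `NA` missing), one
#'   per bank item.
#' @param bank List of [item_parameters].
#' @param grid A [make_grid] quadrature grid.
#'
#' @return List with `theta_eap`, `theta_se`, `n_items_observed`,
#'   `all_missing`.
#' @export
eap_score <- function(pattern, bank, grid = make_grid()) {
  validate_bank(bank)
  if (length(pattern) != length(bank))
    stop("pattern must have one entry per bank item", call. = FALSE)
  vals <- matrix(as.integer(pattern), nrow = 1L)
  e <- eap_from_loglik(loglik_matrix(vals, bank, grid), grid)
  n_obs <- sum(!is.na(pattern))
  list(theta_eap = e$theta, theta_se = e$se, n_items_observed = n_obs,
       all_missing = n_obs == 0L)
}

#' Latent-trait value to T-score
#'
#' The standardized reporting metric: reference-population mean 50, SD 10,
#' so `T = 50 + 10 * theta`.
#'
#' @param theta Numeric vector of finite latent-trait values.
#' @return `50 + 10 * theta`.
#' @examples
#' theta_to_t(0)      # 50
#' theta_to_t(-0.74)  # 42.6
#' @export
theta_to_t <- function(theta) {
  if (anyNA(theta) || any(!is.finite(theta)))
    stop("theta must be finite", call. = FALSE)
  50 + 10 * theta
}

# Score all persons of one instrument; drops zero-observed persons.
score_instrument <- function(rm, bank, grid, method, instrument_label) {
  validate_bank(bank)
  vals <- instrument_values(rm, bank)
  n_obs <- rowSums(!is.na(vals))
  keep <- n_obs > 0L
  dropped <- rm$person_ids[!keep]
  e <- eap_from_loglik(loglik_matrix(vals[keep, , drop = FALSE], bank, grid),
                       grid)
  out <- data.frame(person_id = rm$person_ids[keep],
                    instrument = instrument_label,
                    method = method,
                    theta = e$theta, theta_se = e$se,
                    t_score = theta_to_t(e$theta), t_se = 10 * e$se,
                    n_items_observed = n_obs[keep],
                    stringsAsFactors = FALSE)
  attr(out, "dropped_persons") <- dropped
  out
}

#' Item-level linking: EAP T-scores from the linked instrument alone
#'
#' Scores every person on the linked (10-item) instrument using its fixed
#' original-metric item parameters -- linking approach 1. Persons with no
#' observed linked item are excluded (recorded in the `dropped_persons`
#' attribute).
#'
#' @param rm A [response_matrix] containing the linked instrument's columns.
#' @param linked_params List of [item_parameters] for the linked items.
#' @param grid Quadrature grid.
#'
#' @return Data frame of person scores: `person_id, instrument, method,
#'   theta, theta_se, t_score, t_se, n_items_observed`.
#' @export
item_level_link <- function(rm, linked_params, grid = make_grid()) {
  score_instrument(rm, linked_params, grid, "item-level linking", "linked")
}

#' Observed benchmark: EAP T-scores from the 20-item anchor instrument
#'
#' The directly observed T-scores from the anchor short form, against which
#' all linked scores are compared.
#'
#' @inheritParams item_level_link
#' @param anchor_params List of [item_parameters] for the anchor items.
#' @return Data frame of person scores (see [item_level_link]).
#' @export
observed_benchmark <- function(rm, anchor_params, grid = make_grid()) {
  score_instrument(rm, anchor_params, grid, "observed benchmark", "anchor")
}

#' Write person scores to CSV
#'
#' @param scores A person-score data frame.
#' @param path File path.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
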