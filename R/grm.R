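# Core graded-response-model machinery: item parameters, category
# probabilities, pattern likelihoods and the quadrature representation of the
# latent prior. Everything downstream (scoring, crosswalk, calibration,
# synthetic data) builds on these primitives.

#' Graded response model item parameters
#'
#' Container for one ordered polytomous item in the slope--threshold
#' parameterization of the graded response model (GRM). The probability of
#' responding in category `k` or above is `plogis(a * (theta - b[k - 1]))`,
#' in the pure logistic metric (no 1.7 scaling constant) -- the convention of
#' the PROMIS calibrations this package links to.
#'
#' @param item_id Single character string identifying the item.
#' @param a Discrimination (slope), a positive finite scalar.
#' @param b Numeric vector of strictly increasing category thresholds on the
#'   latent metric. The item has `length(b) + 1` categories, coded
#'   `1..K` to mirror instrument scoring.
#' @param instrument Optional instrument label, `"anchor"` or `"linked"`.
#'
#' @return An object of class `item_parameters`: a list with elements
#'   `item_id`, `a`, `b`, `K`, `instrument`.
#' @examples
#' it <- item_parameters("pf01", a = 2, b = c(-1, 1))
#' category_probabilities(it, 0)
#' @export
item_parameters <- function(item_id, a, b, instrument = NA_character_) {
  if (!is.character(item_id) || length(item_id) != 1L || is.na(item_id))
    stop("item_id must be a single string", call. = FALSE)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop(sprintf("item '%s': discrimination must be a positive finite scalar",
                 item_id), call. = FALSE)
  b <- as.numeric(b)
  if (length(b) < 1L || anyNA(b) || any(!is.finite(b)))
    stop(sprintf("item '%s': thresholds must be finite", item_id),
         call. = FALSE)
  if (length(b) > 1L && any(diff(b) <= 0))
    stop(sprintf("item '%s': thresholds must be strictly increasing", item_id),
         call. = FALSE)
  structure(list(item_id = item_id, a = as.numeric(a), b = b,
                 K = length(b) + 1L, instrument = instrument),
            class = "item_parameters")
}

#' @export
print.item_parameters <- function(x, ...) {
  cat(sprintf("<item %s (%s): K=%d, a=%.3f, b=[%s]>\n", x$item_id,
              x$instrument, x$K, x$a, paste(sprintf("%.3f", x$b),
                                            collapse = ", ")))
  invisible(x)
}

# Validate a bank: a plain list of item_parameters objects.
validate_bank <- function(bank) {
  if (!is.list(bank) || length(bank) == 0L)
    stop("item bank must be a non-empty list of item_parameters",
         call. = FALSE)
  ok <- vapply(bank, inherits, logical(1), "item_parameters")
  if (!all(ok))
    stop("item bank elements must all be item_parameters objects",
         call. = FALSE)
  ids <- vapply(bank, `[[`, character(1), "item_id")
  if (anyDuplicated(ids))
    stop("duplicated item_id in bank", call. = FALSE)
  invisible(bank)
}

bank_ids <- function(bank) vapply(bank, `[[`, character(1), "item_id")
bank_K   <- function(bank) vapply(bank, `[[`, integer(1), "K")

#' Category response probabilities of a GRM item
#'
#' @param item An [item_parameters] object.
#' @param thetas Numeric vector of latent-trait values.
#'
#' @return A `length(thetas) x K` matrix of category probabilities; each row
#'   sums to 1.
#' @export
category_probabilities <- function(item, thetas) {
  if (!inherits(item, "item_parameters"))
    stop("item must be an item_parameters object", call. = FALSE)
  thetas <- as.numeric(thetas)
  if (length(thetas) == 0L || anyNA(thetas) || any(!is.finite(thetas)))
    stop("thetas must be finite", call. = FALSE)
  # P(X >= k + 1 | theta), columns k = 1..K-1; strictly decreasing in k
  cum <- stats::plogis(item$a * outer(thetas, item$b, "-"))
  P <- cbind(1, cum) - cbind(cum, 0)
  dimnames(P) <- list(NULL, paste0("cat", seq_len(item$K)))
  P
}

# log-probability table, K x G, floored away from log(0)
item_log_probs <- function(item, nodes) {
  t(log(pmax(category_probabilities(item, nodes), 1e-300)))
}

#' Log-likelihood of one response pattern at a latent-trait value
#'
#' Missing responses (NA) contribute nothing (ignorable-missingness
#' contract); an all-missing pattern has log-likelihood 0.
#'
#' @param responses Integer vector of categories (1-based), one per bank
#'   item, `NA` for missing.
#' @param bank List of [item_parameters].
#' @param theta Single finite latent-trait value.
#'
#' @return The log-likelihood (a scalar).
#' @export
pattern_log_likelihood <- function(responses, bank, theta) {
  validate_bank(bank)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    stop("theta must be a single finite value", call. = FALSE)
  if (length(responses) != length(bank))
    stop("responses must have one entry per bank item", call. = FALSE)
  ll <- 0
  for (j in seq_along(bank)) {
    x <- responses[j]
    if (is.na(x)) next
    K <- bank[[j]]$K
    if (x < 1 || x > K || x != round(x))
      stop(sprintf("item '%s': category %s outside 1..%d",
                   bank[[j]]$item_id, format(x), K), call. = FALSE)
    p <- category_probabilities(bank[[j]], theta)[1L, x]
    ll <- ll + log(max(p, 1e-300))
  }
  ll
}

#' Quadrature grid over the latent trait
#'
#' Equally spaced nodes with weights proportional to a normal prior density,
#' renormalized to sum to 1. The default (49 nodes on \[-6, 6\], standard
#' normal) resolves EAP estimates to roughly 1e-3 on the theta scale, far
#' below score-reporting precision (0.1 T-score).
#'
#' @param n_nodes Number of nodes (>= 3).
#' @param bounds Length-2 vector `(lo, hi)`, `lo < hi`.
#' @param prior_mean,prior_sd Normal prior parameters (`prior_sd > 0`).
#'
#' @return An object of class `quadrature_grid` with elements `nodes`,
#'   `weights`, `prior_mean`, `prior_sd`.
#' @export
make_grid <- function(n_nodes = 49L, bounds = c(-6, 6), prior_mean = 0,
                      prior_sd = 1) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 3L)
    stop("n_nodes must be >= 3", call. = FALSE)
  if (length(bounds) != 2L || !all(is.finite(bounds)) ||
      bounds[1] >= bounds[2])
    stop("bounds must be finite with lo < hi", call. = FALSE)
  if (!is.finite(prior_mean) || !is.finite(prior_sd) || prior_sd <= 0)
    stop("prior must have finite mean and positive sd", call. = FALSE)
  nodes <- seq(bounds[1], bounds[2], length.out = as.integer(n_nodes))
  w <- stats::dnorm(nodes, prior_mean, prior_sd)
  w <- w / sum(w)
  structure(list(nodes = nodes, weights = w, prior_mean = prior_mean,
                 prior_sd = prior_sd),
            class = "quadrature_grid")
}

#' @export
print.quadrature_grid <- function(x, ...) {
  cat(sprintf("<quadrature grid: %d nodes on [%g, %g], N(%g, %g) prior>\n",
              length(x$nodes), min(x$nodes), max(x$nodes), x$prior_mean,
              x$prior_sd))
  invisible(x)
}
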