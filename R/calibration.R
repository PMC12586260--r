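# Linking approach 3: re-estimate the linked instrument's item parameters by
# marginal maximum likelihood (EM) with the anchor instrument's parameters
# held fixed. The fixed anchors plus the fixed N(0,1) latent density pin the
# re-estimated parameters to the anchor metric.

#' Starting values for free items
#'
#' Slope 1.5 for every item; thresholds at normal quantiles of the observed
#' cumulative category proportions (clipped to \[-3.5, 3.5\]), which are
#' strictly ordered by construction.
#'
#' @param values Integer matrix of the free items' responses (columns in
#'   bank order), `NA` missing.
#' @param items Data frame describing the columns (`item_id`, `K`,
#'   optionally `instrument`).
#'
#' @return List of [item_parameters] starting values.
#' @export
initialize_free_items <- function(values, items) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(items))
    stop("values must have one column per items row", call. = FALSE)
  instr <- if ("instrument" %in% names(items)) items$instrument
           else rep("linked", nrow(items))
  lapply(seq_len(nrow(items)), function(j) {
    K <- items$K[j]
    x <- values[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0L)
      stop(sprintf("item '%s': no observed responses", items$item_id[j]),
           call. = FALSE)
    props <- tabulate(x, nbins = K) / length(x)
    if (any(props == 1))
      stop(sprintf("item '%s': all responses in one category, thresholds undefined",
                   items$item_id[j]), call. = FALSE)
    cum <- cumsum(props)[-K]
    b <- stats::qnorm(pmin(pmax(cum, 1e-4), 1 - 1e-4))
    b <- pmin(pmax(b, -3.5), 3.5)
    # clipping or empty inner categories can create ties; enforce min gap
    if (K > 2L)
      for (k in 2:(K - 1L)) b[k] <- max(b[k], b[k - 1L] + 1e-3)
    item_parameters(items$item_id[j], 1.5, b, instr[j])
  })
}

# Collapse categories observed fewer than min_count times into the neighbor
# toward the mode; returns remapped values, new K, and the mapping.
collapse_sparse_categories <- function(x, K, min_count = 5L) {
  map <- seq_len(K)  # original category -> current category label
  repeat {
    cur <- sort(unique(map))
    counts <- vapply(cur, function(c) sum(x[!is.na(x)] %in% which(map == c)),
                     integer(1))
    if (length(cur) <= 2L || all(counts >= min_count)) break
    deficient <- cur[which.min(counts)]
    mode_cat <- cur[which.max(counts)]
    pos <- match(deficient, cur)
    target <- if (deficient < mode_cat) cur[pos + 1L] else cur[pos - 1L]
    map[map == deficient] <- target
  }
  cur <- sort(unique(map))
  relabel <- match(map, cur)  # original category -> 1..K_new
  newx <- ifelse(is.na(x), NA_integer_, relabel[x])
  list(values = as.integer(newx), K = length(cur), map = relabel,
       collapsed = length(cur) < K)
}

#' Apply category collapse maps to a response matrix's values
#'
#' @param values Integer matrix.
#' @param maps Named list of integer maps (original category -> collapsed
#'   category) from [calibrate_fixed], named by item id.
#' @return The remapped matrix.
#' @export
apply_category_maps <- function(values, maps) {
  for (id in names(maps)) {
    j <- match(id, colnames(values))
    if (is.na(j)) next
    x <- values[, j]
    values[, j] <- ifelse(is.na(x), NA_integer_, maps[[id]][x])
  }
  values
}

# M-step objective and analytic gradient for one item, on the unconstrained
# scale par = (log a, b1, log gaps). N is the K x G expected count table.
mstep_fn <- function(par, N, nodes) {
  a <- exp(par[1L])
  b <- par[2L] + c(0, cumsum(exp(par[-(1:2)])))
  Pstar <- stats::plogis(a * outer(b, nodes, function(bb, th) th - bb)) # (K-1) x G
  P <- rbind(1, Pstar) - rbind(Pstar, 0)                               # K x G
  -sum(N * log(pmax(P, 1e-300)))
}

mstep_gr <- function(par, N, nodes) {
  a <- exp(par[1L])
  gaps <- exp(par[-(1:2)])
  b <- par[2L] + c(0, cumsum(gaps))
  Km1 <- length(b)
  D <- outer(b, nodes, function(bb, th) th - bb)       # (K-1) x G, theta - b
  Pstar <- stats::plogis(a * D)
  P <- rbind(1, Pstar) - rbind(Pstar, 0)               # K x G
  W <- N / pmax(P, 1e-300)                             # K x G
  Q <- Pstar * (1 - Pstar)                             # (K-1) x G
  # dobj/db_j = -a * sum_g Q_jg (W_jg - W_{j+1,g})
  dW <- W[seq_len(Km1), , drop = FALSE] - W[-1L, , drop = FALSE]
  db <- -a * rowSums(Q * dW)
  # dobj/da = -sum_{j,g} Q_jg (theta_g - b_j) (W_{j+1,g} - W_jg)
  da <- sum(Q * D * dW)
  g <- numeric(length(par))
  g[1L] <- a * da
  g[2L] <- sum(db)
  if (Km1 > 1L)
    for (i in seq_len(Km1 - 1L))
      g[2L + i] <- gaps[i] * sum(db[(i + 1L):Km1])
  g
}

optimize_item <- function(N, nodes, item) {
  par0 <- c(log(item$a), item$b[1L],
            if (item$K > 2L) log(diff(item$b)))
  f0 <- mstep_fn(par0, N, nodes)
  opt <- tryCatch(
    stats::optim(par0, mstep_fn, mstep_gr, N = N, nodes = nodes,
                 method = "BFGS",
                 control = list(maxit = 100, reltol = 1e-12)),
    error = function(e) list(par = par0, value = f0))
  if (!is.finite(opt$value) || opt$value > f0) opt <- list(par = par0, value = f0)
  a <- exp(opt$par[1L])
  b <- opt$par[2L] + c(0, cumsum(exp(opt$par[-(1:2)])))
  item_parameters(item$item_id, a, b, item$instrument)
}

#' Fixed-parameter calibration of the linked instrument
#'
#' Marginal-maximum-likelihood EM estimation of the free (linked) items'
#' GRM parameters with the anchor items' parameters held fixed and the
#' latent density fixed at the grid prior (N(0,1) by default; fixing both is
#' what transfers the anchor metric). E-step: per-person posterior weights
#' over the quadrature grid using all observed items. M-step: per free item,
#' quasi-Newton maximization of the expected complete-data log-likelihood on
#' the unconstrained scale (log slope, first threshold, log threshold gaps),
#' safeguarded so the objective never worsens. Stops when the largest
#' absolute parameter change falls below `tol`.
#'
#' Free-item categories observed fewer than `min_cat_count` times are
#' collapsed into the neighboring category toward the mode before
#' estimation (keeps thresholds identifiable at clinical sample sizes); the
#' mapping is returned so the same recoding can be applied before scoring
#' with the re-estimated parameters.
#'
#' @param rm A [response_matrix] holding both instruments.
#' @param anchor_params Fixed anchor bank (returned unchanged).
#' @param init Optional starting values for the free items (defaults to
#'   [initialize_free_items] on the observed margins).
#' @param grid Quadrature grid (its prior is the fixed latent density).
#' @param tol Convergence tolerance on the max absolute parameter change.
#' @param max_cycles Maximum EM cycles.
#' @param min_cat_count Sparse-category collapse threshold.
#'
#' @return An object of class `calibration_result`: list with
#'   `free_item_params`, `anchor_params` (value-identical copy of the
#'   input), `loglik_trace` (observed-data log-likelihood per cycle,
#'   nondecreasing), `converged`, `n_cycles`, `max_param_change_final`,
#'   `category_maps` (collapse maps for items that were collapsed),
#'   `dropped_persons`.
#' @export
calibrate_fixed <- function(rm, anchor_params, init = NULL,
                            grid = make_grid(), tol = 1e-4,
                            max_cycles = 500L, min_cat_count = 5L) {
  validate_bank(anchor_params)
  anchor_ids <- bank_ids(anchor_params)
  free_rows <- rm$items[!(rm$items$item_id %in% anchor_ids), , drop = FALSE]
  if (nrow(free_rows) == 0L)
    stop("no free items: every response column is an anchor", call. = FALSE)
  A_vals <- instrument_values(rm, anchor_params)
  F_vals <- rm$values[, free_rows$item_id, drop = FALSE]

  keep <- rowSums(!is.na(A_vals)) + rowSums(!is.na(F_vals)) > 0L
  dropped <- rm$person_ids[!keep]
  if (length(dropped))
    message(sprintf("calibrate_fixed: dropping %d person(s) with no observed items",
                    length(dropped)))
  A_vals <- A_vals[keep, , drop = FALSE]
  F_vals <- F_vals[keep, , drop = FALSE]

  # sparse-category collapse on free items
  category_maps <- list()
  K_new <- free_rows$K
  for (j in seq_len(ncol(F_vals))) {
    cs <- collapse_sparse_categories(F_vals[, j], free_rows$K[j],
                                     min_cat_count)
    if (cs$collapsed) {
      warning(sprintf("item '%s': sparse categories collapsed (%d -> %d)",
                      free_rows$item_id[j], free_rows$K[j], cs$K),
              call. = FALSE)
      category_maps[[free_rows$item_id[j]]] <- cs$map
      F_vals[, j] <- cs$values
      K_new[j] <- cs$K
    }
  }
  free_rows$K <- K_new

  free <- if (is.null(init)) initialize_free_items(F_vals, free_rows)
          else { validate_bank(init); init }
  if (length(free) != nrow(free_rows))
    stop("init must supply one item per free column", call. = FALSE)

  nodes <- grid$nodes
  G <- length(nodes)
  n <- nrow(F_vals)
  LA <- loglik_matrix(A_vals, anchor_params, grid)   # fixed across cycles
  # per-item response indicator matrices (n x K), NA rows all-zero
  ind <- lapply(seq_along(free), function(j) {
    x <- F_vals[, j]
    M <- matrix(0, n, free[[j]]$K)
    obs <- which(!is.na(x))
    M[cbind(obs, x[obs])] <- 1
    M
  })

  loglik_trace <- numeric(0)
  converged <- FALSE
  max_change <- Inf
  cycle <- 0L
  while (cycle < max_cycles) {
    cycle <- cycle + 1L
    LL <- LA + loglik_matrix(F_vals, free, grid)
    e <- eap_from_loglik(LL, grid)
    loglik_trace <- c(loglik_trace, sum(e$log_marginal))
    lw <- sweep(LL, 2L, log(grid$weights), "+")
    post <- exp(lw - apply(lw, 1L, max))
    post <- post / rowSums(post)                     # n x G
    new_free <- free
    max_change <- 0
    for (j in seq_along(free)) {
      N <- crossprod(ind[[j]], post)                 # K x G expected counts
      new_free[[j]] <- optimize_item(N, nodes, free[[j]])
      max_change <- max(max_change,
                        abs(new_free[[j]]$a - free[[j]]$a),
                        abs(new_free[[j]]$b - free[[j]]$b))
    }
    free <- new_free
    if (max_change < tol) { converged <- TRUE; break }
  }
  # final observed-data log-likelihood under the returned parameters
  LL <- LA + loglik_matrix(F_vals, free, grid)
  loglik_trace <- c(loglik_trace,
                    sum(eap_from_loglik(LL, grid)$log_marginal))

  structure(list(free_item_params = free,
                 anchor_params = anchor_params,
                 loglik_trace = loglik_trace,
                 converged = converged,
                 n_cycles = cycle,
                 max_param_change_final = max_change,
                 category_maps = category_maps,
                 dropped_persons = dropped),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<fixed-parameter calibration: %d free items, %d cycles, %s, final loglik %.3f>\n",
              length(x$free_item_params), x$n_cycles,
              if (x$converged) "converged" else "NOT converged",
              utils::tail(x$loglik_trace, 1)))
  invisible(x)
}

#' Score the linked instrument with re-estimated parameters
#'
#' Convenience wrapper: applies any sparse-category collapse maps recorded
#' during calibration, then pattern-EAP scores the linked items under the
#' re-estimated parameters (linking approach 3).
#'
#' @param rm A [response_matrix].
#' @param calib A [calibrate_fixed] result.
#' @param grid Quadrature grid.
#' @return Data frame of person scores, method `"IRT re-estimation"`.
#' @export
reestimated_link <- function(rm, calib, grid = make_grid()) {
  if (!inherits(calib, "calibration_result"))
    stop("calib must be a calibration_result", call. = FALSE)
  vals <- rm$values
  if (length(calib$category_maps))
    vals <- apply_category_maps(vals, calib$category_maps)
  rm2 <- rm
  rm2$values <- vals
  rm2$items$K[match(names(calib$category_maps), rm2$items$item_id)] <-
    vapply(calib$category_maps, max, integer(1))
  out <- score_instrument(rm2, calib$free_item_params, grid,
                          "IRT re-estimation", "linked")
  out
}
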