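# Pre-linking assumption screening: unidimensionality diagnostics on the
# polychoric correlation matrix (one-factor ULS fit, exploratory bifactor
# ECV / omega-hierarchical via Schmid-Leiman) and DIF screening by ordinal
# logistic regression with the Nagelkerke R^2-change criterion.

# --- bivariate normal CDF -------------------------------------------------

# Vectorized standard bivariate normal CDF P(X <= h, Y <= k; rho), via
# Gauss-Legendre quadrature on the sin-substituted correlation-parameter
# integral (removes the sqrt singularity at |t| = 1):
#   Phi2 = Phi(h) Phi(k)
#        + (1/2pi) Int_0^asin(rho) exp(-(h^2 + k^2 - 2 h k sin f)/(2 cos^2 f)) df
# Accuracy ~1e-10 for |rho| <= 0.999 with 48 nodes. +/-Inf in h or k allowed.
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(h, n); k <- rep_len(k, n); rho <- rep_len(rho, n)
  out <- stats::pnorm(h) * stats::pnorm(k)
  fin <- is.finite(h) & is.finite(k) & rho != 0
  if (any(fin)) {
    gl <- pracma::gaussLegendre(48L, 0, 1)
    up <- asin(pmin(pmax(rho[fin], -1), 1))
    hh <- h[fin]; kk <- k[fin]
    add <- numeric(sum(fin))
    for (i in seq_along(gl$x)) {
      f <- up * gl$x[i]
      cf2 <- cos(f)^2
      add <- add + gl$w[i] *
        exp(-(hh^2 + kk^2 - 2 * hh * kk * sin(f)) / (2 * cf2))
    }
    out[fin] <- out[fin] + up * add / (2 * pi)
  }
  pmin(pmax(out, 0), 1)
}

# --- polychoric correlations ----------------------------------------------

# Two-step polychoric for one pair: thresholds from the pairwise-complete
# marginals, rho by 1-D likelihood maximization on the open (-1, 1).
polychoric_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, fallback = TRUE))
  tab <- table(factor(x, levels = sort(unique(x))),
               factor(y, levels = sort(unique(y))))
  tx <- stats::qnorm(cumsum(rowSums(tab)) / sum(tab))
  ty <- stats::qnorm(cumsum(colSums(tab)) / sum(tab))
  tx <- c(-Inf, tx[-length(tx)], Inf)
  ty <- c(-Inf, ty[-length(ty)], Inf)
  nr <- nrow(tab); nc <- ncol(tab)
  hg <- matrix(rep(tx, nc + 1L), nr + 1L, nc + 1L)
  kg <- matrix(rep(ty, each = nr + 1L), nr + 1L, nc + 1L)
  negll <- function(r) {
    Fg <- matrix(pbvnorm(as.vector(hg), as.vector(kg), r), nr + 1L, nc + 1L)
    pr <- Fg[-1L, -1L] - Fg[-(nr + 1L), -1L] - Fg[-1L, -(nc + 1L)] +
      Fg[-(nr + 1L), -(nc + 1L)]
    -sum(tab * log(pmax(pr, 1e-12)))
  }
  opt <- stats::optimize(negll, c(-1 + 1e-9, 1 - 1e-9), tol = 1e-7)
  list(rho = opt$minimum, fallback = FALSE)
}

#' Polychoric correlation matrix of ordinal responses
#'
#' Two-step maximum-likelihood estimate per item pair: thresholds from the
#' pairwise-complete marginal proportions, then the correlation by 1-D
#' likelihood maximization. Pairs whose contingency structure leaves the
#' correlation inestimable fall back to the Spearman correlation with a
#' warning.
#'
#' @param values Integer matrix (persons x items) or a [response_matrix].
#'
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
polychoric_matrix <- function(values) {
  if (inherits(values, "response_matrix")) values <- values$values
  values <- as.matrix(values)
  p <- ncol(values)
  if (p < 2L) stop("need at least two items", call. = FALSE)
  R <- diag(1, p)
  dimnames(R) <- list(colnames(values), colnames(values))
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    pc <- polychoric_pair(values[, i], values[, j])
    rho <- pc$rho
    if (pc$fallback || is.na(rho)) {
      warning(sprintf("pair (%d, %d): polychoric inestimable, Spearman fallback",
                      i, j), call. = FALSE)
      rho <- stats::cor(values[, i], values[, j], method = "spearman",
                        use = "pairwise.complete.obs")
    }
    R[i, j] <- R[j, i] <- rho
  }
  R
}

# --- ULS factor extraction ------------------------------------------------

# Clip eigenvalues so a correlation matrix is usable; re-standardize.
repair_psd <- function(R, eps = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(list(R = R, repaired = FALSE))
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% (v * t(e$vectors))
  R2 <- stats::cov2cor(R2)
  dimnames(R2) <- dimnames(R)
  list(R = R2, repaired = TRUE)
}

# Iterated-principal-axis (unweighted least squares) extraction of m factors.
uls_factors <- function(R, m, max_iter = 500L, tol = 1e-7,
                        heywood_cap = 0.995) {
  p <- ncol(R)
  h <- tryCatch(pmin(pmax(1 - 1 / diag(solve(R)), 0.1), heywood_cap),
                error = function(e) rep(0.5, p))
  heywood <- FALSE
  L <- NULL
  for (iter in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h
    e <- eigen(Rh, symmetric = TRUE)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
    hn <- rowSums(L^2)
    if (any(hn > heywood_cap)) { heywood <- TRUE; hn <- pmin(hn, heywood_cap) }
    if (max(abs(hn - h)) < tol) { h <- hn; break }
    h <- hn
  }
  # sign convention: each factor's loading sum nonnegative
  for (f in seq_len(m)) if (sum(L[, f]) < 0) L[, f] <- -L[, f]
  list(loadings = L, communalities = h, heywood = heywood)
}

#' One-factor fit of a polychoric correlation matrix
#'
#' Unweighted-least-squares one-factor solution (iterated communalities)
#' with approximate fit indices: a chi-square-type statistic
#' `T = (n - 1) * F` for the model and the independence baseline, from which
#' CFI, TLI, RMSEA and SRMR are formed. `F` is the sum of squared
#' off-diagonal residuals. Heywood communalities are clipped at 0.995 and
#' flagged. Benchmark flags follow the conventional thresholds
#' (CFI > 0.95, TLI > 0.95, RMSEA < 0.06, SRMR < 0.08).
#'
#' @param poly Correlation matrix (e.g. from [polychoric_matrix]).
#' @param n Number of persons behind the matrix.
#'
#' @return List with `loadings`, `fit` (cfi, tli, rmsea, srmr),
#'   `benchmark_flags`, `T_m`, `df_m`, `T_0`, `df_0`, `heywood`,
#'   `psd_repaired`.
#' @export
one_factor_fit <- function(poly, n) {
  p <- ncol(poly)
  if (p < 3L) stop("need at least three items for a one-factor fit",
                   call. = FALSE)
  rp <- repair_psd(poly)
  R <- rp$R
  fa <- uls_factors(R, 1L)
  l <- fa$loadings[, 1L]
  res <- R - tcrossprod(l)
  off <- res[upper.tri(res)]
  Fm <- sum(off^2)
  F0 <- sum(R[upper.tri(R)]^2)
  df_m <- p * (p - 3) / 2
  df_0 <- p * (p - 1) / 2
  Tm <- (n - 1) * Fm
  T0 <- (n - 1) * F0
  eps <- 1e-12
  cfi <- 1 - max(Tm - df_m, 0) / max(T0 - df_0, Tm - df_m, eps)
  tli <- ((T0 / df_0) - (Tm / df_m)) / ((T0 / df_0) - 1)
  rmsea <- sqrt(max(Tm - df_m, 0) / (df_m * (n - 1)))
  srmr <- sqrt(mean(off^2))
  fit <- list(cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr)
  flags <- list(cfi = cfi > 0.95, tli = tli > 0.95, rmsea = rmsea < 0.06,
                srmr = srmr < 0.08)
  list(loadings = l, fit = fit, benchmark_flags = flags,
       T_m = Tm, df_m = df_m, T_0 = T0, df_0 = df_0,
       heywood = fa$heywood, psd_repaired = rp$repaired)
}

#' Exploratory bifactor indices: ECV and omega-hierarchical
#'
#' Schmid-Leiman orthogonalization of an oblique multi-factor ULS solution
#' (promax rotation) with a second-order general factor fitted to the
#' factor correlations. ECV is the general factor's share of the common
#' variance; omega-hierarchical is the general factor's share of total
#' modeled variance plus uniqueness. The default of four group factors
#' mirrors the physical-function subdomains (mobility, dexterity, central
#' regions, complex activities).
#'
#' @param poly Correlation matrix.
#' @param n Number of persons (kept for interface symmetry; the indices are
#'   functions of the matrix alone).
#' @param n_group_factors Number of first-order group factors (>= 1, and
#'   less than a third of the item count).
#'
#' @return List with `ecv`, `omega_h`, `general_loadings`,
#'   `group_loadings`, `benchmark_flags` (ECV > 0.60, omega_h > 0.80).
#' @export
bifactor_ecv_omega <- function(poly, n, n_group_factors = 4L) {
  p <- ncol(poly)
  m <- as.integer(n_group_factors)
  if (m < 1L) stop("n_group_factors must be >= 1", call. = FALSE)
  if (m >= p / 3) stop("too many group factors for the item count",
                       call. = FALSE)
  R <- repair_psd(poly)$R
  if (m > 1L) {
    # drop extracted factors with negligible loading sums of squares:
    # they are rotation-indeterminate noise (e.g. a perfectly
    # unidimensional matrix forced into several factors)
    ss <- colSums(uls_factors(R, m)$loadings^2)
    m <- max(1L, sum(ss > 0.05))
  }
  if (m == 1L) {
    fa <- uls_factors(R, 1L)
    g <- fa$loadings[, 1L]
    B <- matrix(0, p, 0L)
    gamma <- 1
  } else {
    fa <- uls_factors(R, m)
    pro <- stats::promax(fa$loadings)
    P <- unclass(pro$loadings)
    Phi0 <- solve(crossprod(pro$rotmat))
    Phi0 <- (Phi0 + t(Phi0)) / 2
    # rescale so Phi has unit diagonal while preserving P Phi P'
    P <- P %*% diag(sqrt(diag(Phi0)), m)
    Phi <- stats::cov2cor(Phi0)
    gamma <- if (m == 2L) {
      s <- sqrt(min(max(abs(Phi[1L, 2L]), 1e-6), 0.998))
      c(s, sign(Phi[1L, 2L]) * s)
    } else {
      # keep signs: a reflected first-order factor has a negative
      # second-order loading, and the Schmid-Leiman product P %*% gamma
      # needs it that way
      uls_factors(Phi, 1L, heywood_cap = 0.998)$loadings[, 1L]
    }
    gamma <- sign(gamma) * pmin(abs(gamma), 0.999)
    g <- as.vector(P %*% gamma)
    B <- P %*% diag(sqrt(1 - gamma^2), m)
    if (sum(g) < 0) g <- -g
  }
  common <- sum(g^2) + sum(B^2)
  ecv <- sum(g^2) / common
  u <- pmax(1 - rowSums(cbind(g, B)^2), 0)
  denom <- sum(g)^2 + sum(colSums(B)^2) + sum(u)
  omega_h <- sum(g)^2 / denom
  ecv <- min(max(ecv, 0), 1)
  omega_h <- min(max(omega_h, 0), 1)
  list(ecv = ecv, omega_h = omega_h, general_loadings = g,
       group_loadings = B, second_order = gamma,
       benchmark_flags = list(ecv = ecv > 0.60, omega_h = omega_h > 0.80))
}

#' Full dimensionality report
#'
#' Convenience wrapper bundling [polychoric_matrix], [one_factor_fit] and
#' [bifactor_ecv_omega] into one report with benchmark flags.
#'
#' @inheritParams polychoric_matrix
#' @param n_group_factors Passed to [bifactor_ecv_omega].
#' @return List `polychoric_matrix`, `one_factor`, `bifactor`.
#' @export
dimensionality_report <- function(values, n_group_factors = 4L) {
  if (inherits(values, "response_matrix")) values <- values$values
  n <- nrow(values)
  R <- polychoric_matrix(values)
  list(polychoric_matrix = R,
       one_factor = one_factor_fit(R, n),
       bifactor = bifactor_ecv_omega(R, n, n_group_factors))
}

# --- DIF screening --------------------------------------------------------

# Collapse an item's categories until every group-by-category cell is
# populated; merge empty categories into the neighbor with more mass.
collapse_for_groups <- function(y, group) {
  repeat {
    lev <- sort(unique(y[!is.na(y)]))
    if (length(lev) <= 2L) break
    tab <- table(factor(y, levels = lev), group)
    empty <- which(apply(tab, 1L, function(r) any(r == 0)))
    if (!length(empty)) break
    i <- empty[1L]
    target <- if (i == 1L) lev[2L]
              else if (i == length(lev)) lev[i - 1L]
              else if (sum(tab[i - 1L, ]) >= sum(tab[i + 1L, ])) lev[i - 1L]
              else lev[i + 1L]
    y[y == lev[i]] <- target
    y <- match(y, sort(unique(y[!is.na(y)])))  # relabel 1..K'
  }
  y
}

nagelkerke_r2 <- function(ll_model, ll_null, n) {
  (1 - exp((2 / n) * (ll_null - ll_model))) / (1 - exp((2 / n) * ll_null))
}

#' DIF screening by ordinal logistic regression
#'
#' Per item, fits nested proportional-odds models `M1: item ~ trait`,
#' `M2: ~ trait + group`, `M3: ~ trait * group` and computes Nagelkerke
#' pseudo-R-squared against the intercept-only model. The DIF effect size
#' is `delta_r2 = R2(M3) - R2(M1)` (uniform plus non-uniform DIF); items
#' with `delta_r2 > threshold` are flagged. Items whose group-by-category
#' table has empty cells are collapsed for the DIF fit (logged in the
#' output).
#'
#' @param values Integer matrix of item responses (persons x items) or a
#'   [response_matrix].
#' @param group Factor (or coercible) with >= 2 levels, each with >= 20
#'   persons.
#' @param trait Per-person matching trait estimate (e.g. pooled EAP theta).
#' @param threshold Flagging threshold on `delta_r2` (default 0.03).
#'
#' @return Data frame, one row per item: log-likelihoods and Nagelkerke R2
#'   of M1/M2/M3, `delta_r2`, `flagged`, `collapsed`.
#' @export
dif_screen <- function(values, group, trait, threshold = 0.03) {
  if (inherits(values, "response_matrix")) values <- values$values
  values <- as.matrix(values)
  group <- factor(group)
  if (nlevels(group) < 2L)
    stop("group must have at least two levels", call. = FALSE)
  if (any(table(group) < 20L))
    stop("every group level needs at least 20 persons", call. = FALSE)
  if (length(trait) != nrow(values) || anyNA(trait) || any(!is.finite(trait)))
    stop("trait must be finite, one value per person", call. = FALSE)

  fit_polr <- function(formula, dat) {
    tryCatch(
      suppressWarnings(MASS::polr(formula, data = dat, method = "logistic",
                                  Hess = FALSE)),
      error = function(e) NULL)
  }

  res <- lapply(seq_len(ncol(values)), function(j) {
    y0 <- values[, j]
    ok <- !is.na(y0)
    y <- y0[ok]; g <- droplevels(group[ok]); tr <- trait[ok]
    y <- match(y, sort(unique(y)))
    ycol <- collapse_for_groups(y, g)
    collapsed <- length(unique(ycol)) < length(unique(y))
    dat <- data.frame(y = factor(ycol, ordered = TRUE), trait = tr, g = g)
    nn <- nrow(dat)
    tab <- table(dat$y)
    ll0 <- sum(tab * log(tab / nn))
    m1 <- fit_polr(y ~ trait, dat)
    m2 <- fit_polr(y ~ trait + g, dat)
    m3 <- fit_polr(y ~ trait * g, dat)
    if (is.null(m1) || is.null(m2) || is.null(m3)) {
      warning(sprintf("item %d: proportional-odds fit failed, DIF not assessed",
                      j), call. = FALSE)
      return(data.frame(item = j, loglik_m1 = NA, loglik_m2 = NA,
                        loglik_m3 = NA, r2_m1 = NA, r2_m2 = NA, r2_m3 = NA,
                        delta_r2 = NA, flagged = NA, collapsed = collapsed))
    }
    ll <- cummax(c(stats::logLik(m1), stats::logLik(m2), stats::logLik(m3)))
    r2 <- nagelkerke_r2(ll, ll0, nn)
    d <- max(r2[3L] - r2[1L], 0)
    data.frame(item = j, loglik_m1 = ll[1L], loglik_m2 = ll[2L],
               loglik_m3 = ll[3L], r2_m1 = r2[1L], r2_m2 = r2[2L],
               r2_m3 = r2[3L], delta_r2 = d, flagged = d > threshold,
               collapsed = collapsed)
  })
  out <- do.call(rbind, res)
  if (!is.null(colnames(values))) out$item_id <- colnames(values)
  attr(out, "threshold") <- threshold
  out
}
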