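#' Queen-contiguity spatial weights
#'
#' Builds binary contiguity (1 for neighbours, 0 otherwise) and its
#' row-standardized form W from an undirected edge list.  Row standardization
#' is the spatial-econometrics default and gives the eigenvalue-bounded
#' interval for the spatial parameter; the binary matrix is retained.
#' Counties with no neighbours (islands) get zero rows and are listed so
#' callers can exclude them from spatial fits.
#'
#' @param edges `data.frame` with two columns of county ids (one row per
#'   undirected edge), e.g. from [generate_grid_adjacency()].
#' @param ids Character vector of all county ids (defines matrix order).
#' @return Object of class `spatial_weights`: list with `ids`, `n`, sparse
#'   binary adjacency `B`, row-standardized `W`, `islands` (ids), and
#'   `neighbors` (list of integer indices).
#' @export
build_queen_weights <- function(edges, ids) {
  ids <- as.character(ids)
  n <- length(ids)
  a <- match(as.character(edges[[1]]), ids)
  b <- match(as.character(edges[[2]]), ids)
  if (anyNA(a) || anyNA(b))
    stop("edge list references unknown county ids", call. = FALSE)
  if (any(a == b)) stop("self-edges are not allowed", call. = FALSE)
  B <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = 1,
                            dims = c(n, n), use.last.ij = TRUE)
  B <- methods::as(B, "generalMatrix")
  deg <- Matrix::rowSums(B)
  islands <- ids[deg == 0]
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  W <- Matrix::Diagonal(n, inv_deg) %*% B
  nb <- lapply(seq_len(n), function(i) which(B[i, ] != 0))
  structure(list(ids = ids, n = n, B = B, W = W,
                 islands = islands, neighbors = nb),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("Queen-contiguity weights: %d units, %d edges, %d island(s)\n",
              x$n, sum(x$B != 0) / 2, length(x$islands)))
  invisible(x)
}

#' Subset spatial weights to a set of units
#'
#' Restricts the adjacency to the given ids and re-row-standardizes.  Units
#' that become islands under the subset are reported in the result.
#'
#' @param w A `spatial_weights` object.
#' @param keep_ids Ids to retain (order preserved as given).
#' @return A new `spatial_weights` object.
#' @export
subset_weights <- function(w, keep_ids) {
  keep_ids <- as.character(keep_ids)
  idx <- match(keep_ids, w$ids)
  if (anyNA(idx)) stop("keep_ids not all present in weights", call. = FALSE)
  B <- w$B[idx, idx, drop = FALSE]
  deg <- Matrix::rowSums(B)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  W <- Matrix::Diagonal(length(idx), inv_deg) %*% B
  nb <- lapply(seq_along(idx), function(i) which(B[i, ] != 0))
  structure(list(ids = keep_ids, n = length(idx), B = B, W = W,
                 islands = keep_ids[deg == 0], neighbors = nb),
            class = "spatial_weights")
}

# Real eigenvalues of the row-standardized W via similarity:
# W = D^{-1} B is similar to the symmetric D^{-1/2} B D^{-1/2}.
# Requires no islands (deg > 0 for all rows).
weights_eigenvalues <- function(w) {
  deg <- Matrix::rowSums(w$B)
  if (any(deg == 0))
    stop("weights contain islands; exclude them before spatial estimation",
         call. = FALSE)
  d <- 1 / sqrt(deg)
  S <- Matrix::Diagonal(w$n, d) %*% w$B %*% Matrix::Diagonal(w$n, d)
  eigen(as.matrix(S), symmetric = TRUE, only.values = TRUE)$values
}

#' Moran's I global spatial autocorrelation
#'
#' Computes `I = (n / S0) * (z' A z) / (z' z)` with `z` the demeaned values
#' and `A` the weight matrix (`S0` its total weight; `S0 = n` for
#' row-standardized weights with no islands).  Inference is provided both by
#' the normal approximation under the normality assumption and by a seeded
#' permutation test (random relabelling of values across units).
#'
#' @param values Numeric vector, one per unit in `w` (not all equal).
#' @param w A `spatial_weights` object without islands.
#' @param n_permutations Number of random relabelings (default 999).
#' @param alternative `"greater"` (default, positive autocorrelation),
#'   `"less"`, or `"two.sided"`.
#' @return Object of class `moran_result`: list with `I`, `expected`
#'   (`-1/(n-1)`), `z_norm`, `p_norm`, `p_perm`, `n_permutations`.
#' @export
morans_i <- function(values, w, n_permutations = 999,
                     alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- w$n
  if (n < 3) stop("need at least 3 units", call. = FALSE)
  if (length(values) != n) stop("values/weights length mismatch", call. = FALSE)
  if (length(w$islands) > 0)
    stop("exclude islands before computing Moran's I", call. = FALSE)
  z <- values - mean(values)
  if (all(z == 0)) stop("values are constant; Moran's I undefined", call. = FALSE)
  A <- w$W
  S0 <- sum(A)
  denom <- sum(z^2)
  I_obs <- (n / S0) * as.numeric(Matrix::crossprod(z, A %*% z)) / denom
  expected <- -1 / (n - 1)

  # normal approximation (normality assumption)
  S1 <- sum((A + Matrix::t(A))^2) / 2
  S2 <- sum((Matrix::rowSums(A) + Matrix::colSums(A))^2)
  var_norm <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - expected^2
  z_norm <- (I_obs - expected) / sqrt(var_norm)
  p_norm <- switch(alternative,
                   greater = stats::pnorm(z_norm, lower.tail = FALSE),
                   less = stats::pnorm(z_norm),
                   two.sided = 2 * stats::pnorm(abs(z_norm), lower.tail = FALSE))

  # permutation test: columns of Z are random relabelings of z
  p_perm <- NA_real_
  if (n_permutations > 0) {
    Z <- vapply(seq_len(n_permutations), function(i) z[sample.int(n)],
                numeric(n))
    I_perm <- (n / S0) * Matrix::colSums(Z * (A %*% Z)) / denom
    p_perm <- switch(alternative,
      greater = (1 + sum(I_perm >= I_obs)) / (n_permutations + 1),
      less = (1 + sum(I_perm <= I_obs)) / (n_permutations + 1),
      two.sided = (1 + sum(abs(I_perm - expected) >= abs(I_obs - expected))) /
        (n_permutations + 1))
  }
  structure(list(I = I_obs, expected = expected, z_norm = z_norm,
                 p_norm = p_norm, p_perm = p_perm,
                 n_permutations = n_permutations,
                 alternative = alternative),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), z = %.3f, p_norm = %.4g, p_perm = %.4g\n",
              x$I, x$expected, x$z_norm, x$p_norm, x$p_perm))
  invisible(x)
}

#' Ordinary least squares fit
#'
#' QR-based least squares with a rank check; the baseline for the spatial
#' dependence diagnostics.
#'
#' @param y Response vector.
#' @param X Design matrix including an intercept column.
#' @return List with `coefficients`, `residuals`, `fitted`, `sigma2`
#'   (`e'e / n`, the ML variance), `df_sigma2` (`e'e / (n - k)`), `n`, `k`.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  fitted <- as.numeric(X %*% beta)
  e <- y - fitted
  n <- length(y)
  list(coefficients = beta, residuals = e, fitted = fitted,
       sigma2 = sum(e^2) / n, df_sigma2 = sum(e^2) / (n - ncol(X)),
       n = n, k = ncol(X))
}

#' Lagrange multiplier diagnostics for spatial dependence
#'
#' Standard (non-robust) LM tests against spatial error and spatial lag
#' alternatives, from the OLS residuals:
#' `LM_err = (e'We / s2)^2 / T` with `T = tr(W'W + WW)` and `s2 = e'e/n`;
#' `LM_lag = (e'Wy / s2)^2 / D` with
#' `D = (WXb)' M (WXb) / s2 + T`, `M = I - X(X'X)^{-1}X'`.
#' Both statistics are referred to chi-square with 1 df.
#'
#' @param y Response vector.
#' @param X Design matrix with intercept.
#' @param w `spatial_weights` (row-standardized, no islands).
#' @return List with `lm_error`, `lm_lag`, each `(statistic, p_value)`,
#'   plus the OLS fit.
#' @export
lm_diagnostics <- function(y, X, w) {
  if (length(w$islands) > 0)
    stop("exclude islands before LM diagnostics", call. = FALSE)
  fit <- ols_fit(y, X)
  e <- fit$residuals
  n <- fit$n
  W <- w$W
  s2 <- fit$sigma2
  T_ <- sum(Matrix::t(W) * W) + sum(W * W)   # tr(W'W) + tr(WW)
  eWe <- as.numeric(Matrix::crossprod(e, W %*% e))
  lm_err <- (eWe / s2)^2 / T_

  Wy <- as.numeric(W %*% y)
  eWy <- sum(e * Wy)
  WXb <- as.numeric(W %*% fit$fitted)
  # M v = v - X (X'X)^{-1} X' v via OLS projection
  proj <- ols_fit(WXb, as.matrix(X))
  MWXb <- proj$residuals
  D <- sum(MWXb^2) / s2 + T_
  lm_lag <- (eWy / s2)^2 / D
  list(lm_error = list(statistic = lm_err,
                       p_value = stats::pchisq(lm_err, 1, lower.tail = FALSE)),
       lm_lag = list(statistic = lm_lag,
                     p_value = stats::pchisq(lm_lag, 1, lower.tail = FALSE)),
       ols = fit)
}

# Full spatial-error log-likelihood at (beta, lambda, sigma2); eigenvalues of
# W supply ln|I - lambda W| = sum ln(1 - lambda w_i).
sem_loglik <- function(beta, lambda, sigma2, y, X, W, omega) {
  n <- length(y)
  Ay <- y - lambda * as.numeric(W %*% y)
  AX <- X - lambda * as.matrix(W %*% X)
  e <- Ay - as.numeric(AX %*% beta)
  -n / 2 * log(2 * pi * sigma2) + sum(log(1 - lambda * omega)) -
    sum(e^2) / (2 * sigma2)
}

#' Maximum-likelihood spatial error model
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ N(0, sigma2 I)` by
#' maximum likelihood.  For fixed `lambda` the spatially filtered regression
#' `(y - lambda W y) ~ (X - lambda W X)` is solved by least squares; the
#' concentrated log-likelihood, whose Jacobian term `ln|I - lambda W|` is
#' computed from the (cached) eigenvalues of the row-standardized W as
#' `sum(log(1 - lambda w_i))`, is maximized over the eigenvalue-bounded
#' interval by 1-D bounded search.  Standard errors come from the observed
#' information (numerical Hessian of the full log-likelihood at the optimum).
#'
#' @param y Response (here: log county fluoride concentration).
#' @param X Design matrix with intercept, no islands among units.
#' @param w `spatial_weights` object.
#' @param eigenvalues Optional precomputed eigenvalues of W (cached across
#'   fits on the same weights).
#' @param tol Optimizer tolerance on lambda (default 1e-8).
#' @param fixed_lambda Optional: skip optimization and evaluate the model at
#'   this spatial parameter (`fixed_lambda = 0` reproduces OLS exactly).
#' @return Object of class `sem_fit`: `coefficients`, `se`, `lambda`,
#'   `se_lambda`, `sigma2`, `loglik`, `loglik0` (at lambda = 0), `n`,
#'   `interval`, `convergence_warning`.
#' @export
fit_spatial_error <- function(y, X, w, eigenvalues = NULL, tol = 1e-8,
                              fixed_lambda = NULL) {
  if (length(w$islands) > 0)
    stop("exclude islands before fitting the spatial error model", call. = FALSE)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (length(y) != w$n) stop("y/weights length mismatch", call. = FALSE)
  omega <- if (is.null(eigenvalues)) weights_eigenvalues(w) else eigenvalues
  lo <- 1 / min(omega) + 1e-8
  hi <- 1 / max(omega) - 1e-8
  W <- w$W
  Wy <- as.numeric(W %*% y)
  WX <- as.matrix(W %*% X)

  conc <- function(lambda) {
    Ay <- y - lambda * Wy
    AX <- X - lambda * WX
    f <- ols_fit(Ay, AX)
    -n / 2 * (log(2 * pi) + 1) - n / 2 * log(f$sigma2) +
      sum(log(1 - lambda * omega))
  }
  ll0 <- conc(0)
  if (is.null(fixed_lambda)) {
    opt <- stats::optimize(conc, interval = c(lo, hi), maximum = TRUE, tol = tol)
    lambda_hat <- opt$maximum
    # guard: the concentrated likelihood must beat (or match) lambda = 0
    if (opt$objective < ll0) lambda_hat <- 0
    at_boundary <- (hi - lambda_hat) < 1e-4 || (lambda_hat - lo) < 1e-4
  } else {
    stopifnot(fixed_lambda > lo, fixed_lambda < hi)
    lambda_hat <- fixed_lambda
    at_boundary <- FALSE
  }

  Ay <- y - lambda_hat * Wy
  AX <- X - lambda_hat * WX
  f <- ols_fit(Ay, AX)
  beta_hat <- f$coefficients
  sigma2_hat <- f$sigma2
  loglik <- conc(lambda_hat)

  # observed information via numerical Hessian of the full log-likelihood
  k <- ncol(X)
  par0 <- c(beta_hat, lambda_hat, sigma2_hat)
  nll <- function(p) {
    lam <- p[k + 1]; s2 <- p[k + 2]
    if (s2 <= 0 || lam <= lo || lam >= hi) return(Inf)
    -sem_loglik(p[seq_len(k)], lam, s2, y, X, W, omega)
  }
  se <- rep(NA_real_, k); se_lambda <- NA_real_
  H <- tryCatch(pracma::hessian(nll, par0), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      if (all(dv[seq_len(k)] > 0)) se <- sqrt(dv[seq_len(k)])
      if (dv[k + 1] > 0) se_lambda <- sqrt(dv[k + 1])
    }
  }
  if (any(is.na(se))) {
    # fall back on the GLS covariance for beta (exact block of the
    # information matrix: beta is information-orthogonal to (lambda, sigma2))
    XtX <- crossprod(AX)
    se <- sqrt(diag(sigma2_hat * solve(XtX)))
  }
  names(se) <- colnames(X)
  structure(list(coefficients = beta_hat, se = se, lambda = lambda_hat,
                 se_lambda = se_lambda, sigma2 = sigma2_hat,
                 loglik = loglik, loglik0 = ll0, n = n,
                 interval = c(lo, hi),
                 convergence_warning = at_boundary,
                 residuals = Ay - as.numeric(AX %*% beta_hat)),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("Spatial error model (ML), n = %d\n", x$n))
  cat(sprintf("lambda = %.4f (SE %.4f), sigma2 = %.5f, logLik = %.3f\n",
              x$lambda, x$se_lambda, x$sigma2, x$loglik))
  print(data.frame(estimate = x$coefficients, se = x$se))
  if (x$convergence_warning)
    cat("warning: lambda estimate at the boundary of the feasible interval\n")
  invisible(x)
}

#' Geometric mean ratio per 10 percentage points
#'
#' For a model of log concentration with a composition covariate entered as
#' percent/10, the geometric mean ratio per 10 percentage-point higher
#' composition is `exp(beta)` with 95% CI `exp(beta +/- 1.96 SE)`.
#'
#' @param fit A `sem_fit` (or any list with `coefficients` and `se`).
#' @param covariate Name of the covariate.
#' @return List `gmr`, `ci_low`, `ci_high`, `beta`, `se`.
#' @export
gmr_per_10pct <- function(fit, covariate) {
  if (!covariate %in% names(fit$coefficients))
    stop("covariate not in fit: ", covariate, call. = FALSE)
  b <- unname(fit$coefficients[covariate])
  s <- unname(fit$se[covariate])
  list(gmr = exp(b), ci_low = exp(b - 1.96 * s), ci_high = exp(b + 1.96 * s),
       beta = b, se = s)
}

#' Percent change implied by a geometric mean ratio
#'
#' `100 * (GMR - 1)`, applied to the point estimate and CI bounds; for
#' reports the values are rounded to integer percent.
#'
#' @param gmr Geometric mean ratio (> 0).
#' @param ci Optional length-2 vector of CI bounds.
#' @param round_digits Digits for the reported percents (default 0).
#' @return List `pct`, `pct_low`, `pct_high` (rounded), plus `raw` values.
#' @export
percent_change <- function(gmr, ci = NULL, round_digits = 0) {
  stopifnot(gmr > 0)
  raw <- 100 * (gmr - 1)
  out <- list(pct = round(raw, round_digits), raw = raw)
  if (!is.null(ci)) {
    out$pct_low <- round(100 * (ci[1] - 1), round_digits)
    out$pct_high <- round(100 * (ci[2] - 1), round_digits)
    out$raw_low <- 100 * (ci[1] - 1)
    out$raw_high <- 100 * (ci[2] - 1)
  }
  out
}

#' Fit the county composition models
#'
#' For each racial/ethnic composition covariate, restricts to counties with
#' at least `min_count` residents of that group, subsets and
#' re-row-standardizes the weights (dropping any island counties this
#' creates), and fits spatial error models of log county fluoride:
#' Model 1 adjusts for percent of public water from groundwater, population
#' density and socioeconomic vulnerability; Model 2 further adjusts for the
#' population-weighted percent of public water reported fluoridated.
#' Composition enters as percent/`scale` so `exp(beta)` is the geometric mean
#' ratio per `scale` percentage-point higher composition (`scale = 60` is the
#' majority-community sensitivity).
#'
#' @param counties Merged county table: one row per included county with the
#'   outcome column, composition percents and counts, `density`, `svi`,
#'   `pct_groundwater`, `pct_fluoridated`.
#' @param w `spatial_weights` over all counties in `counties$county_id`.
#' @param outcome Column with the county concentration (`"weighted_mean"`
#'   default, `"weighted_p95"` for the upper-tail sensitivity).
#' @param groups Named list mapping a group label to
#'   `c(pct = <percent column>, count = <count column>)`.
#' @param models Integer vector, subset of `c(1, 2)`.
#' @param scale Composition denominator in percentage points (10 or 60).
#' @param min_count Minimum residents of the group per county (default 100).
#' @return Object of class `model_report`: list with `table` (tidy
#'   data.frame: group, model, n, gmr, ci, percent change, lambda) and
#'   `fits` (nested list of `sem_fit`s).
#' @export
run_models <- function(counties, w,
                       outcome = "weighted_mean",
                       groups = default_groups(),
                       models = c(1, 2),
                       scale = 10,
                       min_count = 100) {
  stopifnot(outcome %in% names(counties), scale > 0)
  rows <- list(); fits <- list()
  for (g in names(groups)) {
    pct_col <- groups[[g]][["pct"]]
    cnt_col <- groups[[g]][["count"]]
    sub <- restrict_by_group_count(counties, cnt_col, min_count)
    wg <- subset_weights(w, sub$county_id)
    if (length(wg$islands) > 0) {
      sub <- sub[!sub$county_id %in% wg$islands, , drop = FALSE]
      wg <- subset_weights(w, sub$county_id)
    }
    y <- log(sub[[outcome]])
    if (any(!is.finite(y)))
      stop("non-positive county concentrations; cannot take logs", call. = FALSE)
    ev <- weights_eigenvalues(wg)
    small_n <- nrow(sub) < 30
    for (m in models) {
      X <- cbind(intercept = 1,
                 composition = sub[[pct_col]] / scale,
                 pct_groundwater = sub$pct_groundwater,
                 density = sub$density / 1000,
                 svi = sub$svi)
      if (m == 2 && stats::sd(sub$pct_fluoridated) > 0)
        X <- cbind(X, pct_fluoridated = sub$pct_fluoridated)
      fit <- fit_spatial_error(y, X, wg, eigenvalues = ev)
      gm <- gmr_per_10pct(fit, "composition")
      pc <- percent_change(gm$gmr, c(gm$ci_low, gm$ci_high))
      fits[[g]][[paste0("model", m)]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, model = m, n = nrow(sub),
        gmr = gm$gmr, ci_low = gm$ci_low, ci_high = gm$ci_high,
        pct_change = pc$pct, pct_change_low = pc$pct_low,
        pct_change_high = pc$pct_high,
        lambda = fit$lambda, loglik = fit$loglik,
        small_sample_warning = small_n,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 outcome = outcome, scale = scale),
            class = "model_report")
}

#' Default racial/ethnic group map for the county models
#' @return Named list mapping group labels to percent and count columns.
#' @export
default_groups <- function() {
  list("Hispanic/Latino" = c(pct = "pct_hispanic", count = "count_hispanic"),
       "non-Hispanic Black" = c(pct = "pct_nh_black", count = "count_nh_black"),
       "American Indian/Alaskan Native" = c(pct = "pct_aian", count = "count_aian"),
       "non-Hispanic White" = c(pct = "pct_nh_white", count = "count_nh_white"))
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("Spatial error model report (outcome: log %s, per %g pct pts)\n",
              x$outcome, x$scale))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
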