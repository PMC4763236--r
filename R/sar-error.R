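#' @importFrom stats optimize pnorm sd cor lm coef pt var quantile rnorm
#'   rbinom runif rlnorm cor.test complete.cases setNames
NULL

# Eigenvalues of a row-standardized distance-band weights matrix.
# W = D^-1 A with A symmetric binary, so on the non-isolate block W is
# similar to the symmetric D^-1/2 A D^-1/2 and all eigenvalues are real;
# isolates contribute zeros.
sar_weights_eigenvalues <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  W <- weights$W
  n <- weights$n
  deg <- Matrix::rowSums(W != 0)
  keep <- which(deg > 0)
  if (!length(keep)) return(rep(0, n))
  A <- W[keep, keep, drop = FALSE] != 0
  s <- 1 / sqrt(deg[keep])
  M <- Matrix::Diagonal(x = s) %*% (A * 1) %*% Matrix::Diagonal(x = s)
  ev <- eigen(as.matrix(Matrix::forceSymmetric(M)), symmetric = TRUE,
              only.values = TRUE)$values
  c(ev, rep(0, n - length(keep)))
}

sar_lambda_interval <- function(ev) {
  lo <- if (min(ev) < 0) 1 / min(ev) else -1
  c(lo, 1)
}

#' Concentrated log-likelihood of the SAR error model
#'
#' For the model y = X beta + u, u = lambda W u + eps, eps ~ N(0, sigma^2 I),
#' with A = I - lambda W the profile (concentrated) log-likelihood at a given
#' lambda is
#' \deqn{-(n/2)(\log 2\pi + \log \hat\sigma^2 + 1) + \log|A|}
#' where beta and sigma^2 are replaced by their GLS maximizers
#' \eqn{\hat\beta = (X'A'AX)^{-1} X'A'A y} and
#' \eqn{\hat\sigma^2 = e'A'Ae/n}, \eqn{e = y - X\hat\beta}. The
#' log-determinant is computed from precomputed eigenvalues e_i of W as
#' \eqn{\sum_i \log(1 - \lambda e_i)}.
#'
#' @param lambda spatial error coefficient; must lie in
#'   (1/min(eigenvalues), 1).
#' @param y response vector.
#' @param X design matrix (including any intercept column).
#' @param weights \code{spatial_weights} on the same units.
#' @param ev optional precomputed eigenvalues of the weights matrix.
#' @return the concentrated log-likelihood (scalar).
#' @export
sar_err_loglik <- function(lambda, y, X, weights, ev = NULL) {
  if (is.null(ev)) ev <- sar_weights_eigenvalues(weights)
  iv <- sar_lambda_interval(ev)
  if (lambda <= iv[1] || lambda >= iv[2])
    stop(sprintf("lambda = %g outside admissible interval (%g, %g)",
                 lambda, iv[1], iv[2]))
  W <- weights$W
  n <- length(y)
  X <- as.matrix(X)
  ya <- y - lambda * as.numeric(W %*% y)
  Xa <- X - lambda * as.matrix(W %*% X)
  XtX <- crossprod(Xa)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(Xa)) stop("singular X'A'AX: collinear design")
  beta <- solve(qrX, crossprod(Xa, ya))
  e <- ya - Xa %*% beta
  sigma2 <- sum(e * e) / n
  -(n / 2) * (log(2 * pi) + log(sigma2) + 1) + sum(log(1 - lambda * ev))
}

#' Fit a simultaneous autoregressive spatial-error model by ML
#'
#' Maximizes the concentrated log-likelihood over lambda by bounded 1-D
#' optimization (tolerance 1e-8), then recovers beta and sigma^2 by GLS at
#' the optimum. Standard errors for beta come from the GLS covariance
#' \eqn{\hat\sigma^2 (X'A'AX)^{-1}}; z = beta/SE with two-sided normal
#' p-values. Isolated units (all-zero weight rows) contribute OLS-like rows.
#'
#' @param y response vector (typically area-residualized log10 richness).
#' @param X matrix or data.frame of predictors (no intercept column).
#' @param weights \code{spatial_weights} on the same units.
#' @param ev optional precomputed weight-matrix eigenvalues (reused across
#'   fits on the same weights).
#' @param morans_nperm permutations for the residual Moran's I test (0 =
#'   statistic only).
#' @param lambda_fixed optionally fix lambda instead of maximizing over it
#'   (e.g. 0 for the exact OLS reduction); the reported likelihood is then
#'   the profile value at that lambda.
#' @return An object of class \code{sar_fit}: lambda, beta, se, z, p,
#'   sigma2, loglik, aic (\eqn{-2\ell + 2(p+2)}, counting all regression
#'   coefficients plus lambda and sigma^2), pseudo_r2, resid_moran, fitted,
#'   residuals (innovation-scale), lag_km, n, p_count, se_method.
#' @export
fit_sar_err <- function(y, X, weights, ev = NULL, morans_nperm = 0,
                        lambda_fixed = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X")
  n <- length(y)
  if (nrow(X) != n || weights$n != n) stop("dimension mismatch")
  Xd <- cbind("(Intercept)" = 1, X)
  if (qr(Xd)$rank < ncol(Xd)) {
    stop("rank-deficient design; check collinear columns: ",
         paste(colnames(X), collapse = ", "))
  }
  if (is.null(ev)) ev <- sar_weights_eigenvalues(weights)
  iv <- sar_lambda_interval(ev)
  eps <- 1e-6
  if (is.null(lambda_fixed)) {
    opt <- stats::optimize(function(l) sar_err_loglik(l, y, Xd, weights, ev),
                           lower = iv[1] + eps, upper = iv[2] - eps,
                           maximum = TRUE, tol = 1e-8)
    lambda <- opt$maximum
    loglik <- opt$objective
  } else {
    lambda <- lambda_fixed
    loglik <- sar_err_loglik(lambda, y, Xd, weights, ev)
  }
  W <- weights$W
  ya <- y - lambda * as.numeric(W %*% y)
  Xa <- Xd - lambda * as.matrix(W %*% Xd)
  XtX <- crossprod(Xa)
  beta <- drop(solve(XtX, crossprod(Xa, ya)))
  e_gls <- drop(ya - Xa %*% beta)
  sigma2 <- sum(e_gls^2) / n
  vcv <- sigma2 * solve(XtX)
  se <- sqrt(diag(vcv))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  trend <- drop(Xd %*% beta)
  fitted <- trend + lambda * as.numeric(W %*% (y - trend))
  p_count <- ncol(Xd)
  rm_i <- tryCatch(morans_i(e_gls, weights, nperm = morans_nperm)$I,
                   error = function(e) NA_real_)
  structure(list(
    lambda = lambda, beta = beta, se = se, z = z, p = p,
    sigma2 = sigma2, loglik = loglik,
    aic = -2 * loglik + 2 * (p_count + 2),
    pseudo_r2 = pseudo_r2_values(fitted, y),
    resid_moran = rm_i, fitted = fitted, residuals = e_gls,
    lag_km = weights$lag_km, n = n, p_count = p_count,
    se_method = "gls_covariance",
    isolate_fraction = length(weights$isolates) / n
  ), class = "sar_fit")
}

pseudo_r2_values <- function(fitted, y) {
  if (stats::sd(fitted) == 0) stop("constant predictions: pseudo-r2 undefined")
  stats::cor(fitted, y)^2
}

#' Pseudo r-squared of a SAR fit
#'
#' The squared Pearson correlation between predicted and observed responses.
#' Predictions include the spatial signal by default:
#' \eqn{\hat y = X\hat\beta + \hat\lambda W (y - X\hat\beta)}; set
#' \code{trend_only = TRUE} for the trend component alone.
#'
#' @param fit a \code{sar_fit}.
#' @param y the observed response the model was fitted to.
#' @param X the predictor matrix used in the fit (needed for
#'   \code{trend_only}).
#' @param weights the weights used in the fit.
#' @param trend_only use X beta only.
#' @return squared correlation in \[0, 1\].
#' @export
pseudo_r2 <- function(fit, y, X = NULL, weights = NULL, trend_only = FALSE) {
  stopifnot(inherits(fit, "sar_fit"))
  if (!trend_only) return(pseudo_r2_values(fit$fitted, y))
  if (is.null(X)) stop("X required for trend-only predictions")
  Xd <- cbind(1, as.matrix(X))
  pseudo_r2_values(drop(Xd %*% fit$beta), y)
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("SAR error model: n = %d, lag = %g km\n", x$n, x$lag_km))
  cat(sprintf("  lambda = %.4f  logLik = %.2f  AIC = %.1f  pseudo-r2 = %.3f  residual Moran's I = %.3f\n",
              x$lambda, x$loglik, x$aic, x$pseudo_r2, x$resid_moran))
  tab <- data.frame(beta = x$beta, se = x$se, z = x$z, p = x$p)
  tab$sig <- significance_stars(x$p)
  print(round_df(tab, 4))
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

round_df <- function(d, digits) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], round, digits = digits)
  d
}

#' Select the lag distance by AIC
#'
#' Builds distance-band weights at each candidate lag, fits the SAR error
#' model at each, and returns the lag minimizing AIC together with a
#' diagnostics table (AIC, log-likelihood, lambda, residual Moran's I,
#' isolate fraction per lag).
#'
#' @param y,X response and predictor matrix as in \code{\link{fit_sar_err}}.
#' @param centroids planar km coordinates of the units.
#' @param lags candidate lag distances in km.
#' @return list with \code{best_lag}, \code{table} (one row per candidate),
#'   \code{fit} (the fit at the best lag) and \code{weights} (its weights).
#' @export
select_lag <- function(y, X, centroids, lags = candidate_lags()) {
  if (!length(lags)) stop("no candidate lags supplied")
  rows <- list(); fits <- list(); wts <- list()
  errs <- character()
  for (lag in lags) {
    res <- tryCatch({
      w <- build_distance_band_weights(centroids, lag)
      f <- fit_sar_err(y, X, w)
      list(w = w, f = f)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("lag %g km: %s", lag, conditionMessage(res)))
      next
    }
    key <- as.character(lag)
    fits[[key]] <- res$f; wts[[key]] <- res$w
    rows[[key]] <- data.frame(
      lag_km = lag, aic = res$f$aic, loglik = res$f$loglik,
      lambda = res$f$lambda, resid_moran = res$f$resid_moran,
      isolate_fraction = res$f$isolate_fraction)
  }
  if (!length(rows))
    stop("all candidate lags failed:\n", paste(errs, collapse = "\n"))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- tab$lag_km[which.min(tab$aic)]
  key <- as.character(best)
  list(best_lag = best, table = tab, fit = fits[[key]], weights = wts[[key]],
       failed = errs)
}

#' Compare the selected-predictor model with the full-variable model
#'
#' Fits both nested models at the same weights and reports the change in
#' pseudo-r2 (full minus subset) and both AICs — the robustness check that a
#' small delta-r2 means little is lost by restricting to the selected
#' predictors.
#'
#' @param y response.
#' @param X_top matrix of the selected predictors.
#' @param X_all matrix of all candidate predictors (must contain the
#'   selected columns).
#' @param weights shared \code{spatial_weights}.
#' @return list with \code{delta_r2}, \code{aic_top}, \code{aic_all},
#'   \code{r2_top}, \code{r2_all}, and both fits.
#' @export
compare_full_model <- function(y, X_top, X_all, weights) {
  X_top <- as.matrix(X_top); X_all <- as.matrix(X_all)
  if (!all(colnames(X_top) %in% colnames(X_all)))
    stop("selected columns must be a subset of the full design")
  ev <- sar_weights_eigenvalues(weights)
  fit_top <- fit_sar_err(y, X_top, weights, ev = ev)
  fit_all <- fit_sar_err(y, X_all, weights, ev = ev)
  list(delta_r2 = fit_all$pseudo_r2 - fit_top$pseudo_r2,
       aic_top = fit_top$aic, aic_all = fit_all$aic,
       r2_top = fit_top$pseudo_r2, r2_all = fit_all$pseudo_r2,
       fit_top = fit_top, fit_all = fit_all)
}

#' Check sensitivity to how the county-area effect is removed
#'
#' Compares two ways of handling the area effect: (a) regress log richness
#' on log area first and model the residuals, (b) model raw log richness
#' with log area included as a covariate. Reports the |z|-ranking of the
#' shared predictors under both and flags disagreement on the top predictor.
#'
#' @param log_richness raw log10 richness.
#' @param X predictor matrix (without area).
#' @param log_area log10 county areas.
#' @param weights \code{spatial_weights}.
#' @return list with both fits, both rankings, and \code{agree_top}.
#' @export
area_effect_check <- function(log_richness, X, log_area, weights) {
  X <- as.matrix(X)
  if (stats::sd(log_area) == 0) stop("constant area: rank check failed")
  ev <- sar_weights_eigenvalues(weights)
  y_res <- residualize_on_area(log_richness, log_area)
  fit_resid <- fit_sar_err(y_res, X, weights, ev = ev)
  X_area <- cbind(X, log_area = log_area)
  fit_area <- fit_sar_err(log_richness, X_area, weights, ev = ev)
  shared <- colnames(X)
  rank_of <- function(fit) {
    zz <- abs(fit$z[shared])
    shared[order(-zz)]
  }
  r1 <- rank_of(fit_resid); r2 <- rank_of(fit_area)
  list(fit_residualized = fit_resid, fit_area_covariate = fit_area,
       ranking_residualized = r1, ranking_area_covariate = r2,
       agree_top = identical(r1[1], r2[1]))
}

#' Table-style summary of a SAR fit
#'
#' A per-predictor report mirroring the usual presentation of spatial linear
#' models: z with significance stars (0.05/0.01/0.001), plus AIC, fitted
#' pseudo-r2 and residual Moran's I.
#'
#' @param fit a \code{sar_fit}.
#' @return list ready for JSON serialization.
#' @export
sar_report <- function(fit) {
  stopifnot(inherits(fit, "sar_fit"))
  vars <- names(fit$beta)
  list(
    predictors = lapply(stats::setNames(vars, vars), function(v) {
      list(beta = fit$beta[[v]], se = fit$se[[v]], z = fit$z[[v]],
           p = fit$p[[v]], stars = significance_stars(fit$p[[v]]))
    }),
    lambda = fit$lambda, aic = fit$aic, loglik = fit$loglik,
    pseudo_r2 = fit$pseudo_r2, resid_moran = fit$resid_moran,
    lag_km = fit$lag_km, n = fit$n, se_method = fit$se_method
  )
}
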