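test_that("concentrated likelihood matches the dense-matrix oracle", {
  set.seed(42)
  w <- grid_weights(5, 5, spacing = 50, lag_km = 60)
  n <- 25
  X <- cbind(1, a = rnorm(n), b = rnorm(n))
  y <- simulate_sar_response(X[, -1], c(1, -0.5), 0.4, 0.5, w, intercept = 1)
  ev <- richscape:::sar_weights_eigenvalues(w)
  for (lam in c(-0.6, -0.2, 0, 0.3, 0.5, 0.8)) {
    expect_equal(sar_err_loglik(lam, y, X, w, ev),
                 dense_sar_loglik(lam, y, X, w), tolerance = 1e-8)
  }
  # lambda = 0 equals the OLS profile log-likelihood
  rss <- sum(resid(lm(y ~ X[, -1]))^2)
  expect_equal(sar_err_loglik(0, y, X, w, ev),
               -(n / 2) * (log(2 * pi) + log(rss / n) + 1), tolerance = 1e-10)
  expect_error(sar_err_loglik(1.2, y, X, w, ev), "admissible")
})

test_that("eigenvalue log-determinant equals the dense determinant", {
  set.seed(6)
  for (rep in 1:4) {
    n <- sample(20:60, 1)
    xy <- matrix(runif(2 * n, 0, 250), ncol = 2)
    w <- build_distance_band_weights(xy, 90)
    ev <- richscape:::sar_weights_eigenvalues(w)
    expect_true(all(abs(Im(ev)) == 0))
    for (lam in c(-0.5, 0.2, 0.7)) {
      dense <- determinant(diag(n) - lam * as.matrix(w$W), logarithm = TRUE)
      expect_equal(sum(log(1 - lam * ev)), as.numeric(dense$modulus),
                   tolerance = 1e-8)
    }
  }
})

test_that("fitting data generated without spatial error reduces to OLS", {
  set.seed(12)
  w <- grid_weights(15, 15, spacing = 50, lag_km = 60)
  n <- 225
  X <- cbind(a = rnorm(n), b = runif(n))
  y <- drop(2 + X %*% c(1.2, -0.7) + rnorm(n, 0, 0.4))
  # at lambda = 0 the GLS estimator is exactly OLS
  fit0 <- fit_sar_err(y, X, w, lambda_fixed = 0)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(fit0$beta - ols)), 1e-10)
  # the free fit finds lambda near 0 (its sampling SD is ~sqrt(3/n))
  fit <- fit_sar_err(y, X, w)
  expect_lt(abs(fit$lambda), 3 * sqrt(3 / n))
  expect_lt(max(abs(fit$beta - ols)), 0.05)
  # AIC bookkeeping: -2 loglik + 2 (p_count + 2)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * (fit$p_count + 2))
  expect_equal(fit$z, fit$beta / fit$se)
})

test_that("lambda and beta are recovered on SAR-error data", {
  w <- grid_weights(20, 20, spacing = 50, lag_km = 60)
  ev <- richscape:::sar_weights_eigenvalues(w)
  n <- 400
  lams <- numeric(30); betas <- matrix(0, 30, 2)
  for (i in 1:30) {
    set.seed(300 + i)
    X <- cbind(a = rnorm(n), b = rnorm(n))
    y <- simulate_sar_response(X, c(1.5, -0.8), 0.6, 0.3, w, intercept = 1)
    f <- fit_sar_err(y, X, w, ev = ev)
    lams[i] <- f$lambda
    betas[i, ] <- f$beta[c("a", "b")]
  }
  expect_gt(mean(lams), 0.5)
  expect_lt(mean(lams), 0.7)
  expect_lt(max(abs(colMeans(betas) - c(1.5, -0.8))), 0.01)
})

test_that("the fitted lambda is invariant to unit relabeling", {
  set.seed(9)
  n <- 100
  xy <- matrix(runif(2 * n, 0, 400), ncol = 2)
  w <- build_distance_band_weights(xy, 100)
  X <- cbind(a = rnorm(n))
  y <- simulate_sar_response(X, 0.8, 0.5, 0.4, w)
  fit <- fit_sar_err(y, X, w)
  perm <- sample(n)
  w_p <- build_distance_band_weights(xy[perm, ], 100)
  fit_p <- fit_sar_err(y[perm], X[perm, , drop = FALSE], w_p)
  expect_equal(fit_p$lambda, fit$lambda, tolerance = 1e-6)
  expect_equal(fit_p$beta, fit$beta, tolerance = 1e-6)
})

test_that("pseudo-r2 is a squared correlation with the spatial signal", {
  set.seed(14)
  w <- grid_weights(10, 10, spacing = 50, lag_km = 60)
  n <- 100
  X <- cbind(a = rnorm(n))
  # noise-free linear data: perfect fit
  y0 <- drop(1 + 2 * X[, 1])
  fit0 <- fit_sar_err(y0 + rnorm(n, 0, 1e-8), X, w)
  expect_equal(fit0$pseudo_r2, 1, tolerance = 1e-6)

  y <- simulate_sar_response(X, 1, 0.5, 0.6, w)
  fit <- fit_sar_err(y, X, w)
  expect_gte(fit$pseudo_r2, 0)
  expect_lte(fit$pseudo_r2, 1)
  # matches the definition computed by hand
  yhat <- drop(cbind(1, X) %*% fit$beta) +
    fit$lambda * as.numeric(w$W %*% (y - drop(cbind(1, X) %*% fit$beta)))
  expect_equal(fit$pseudo_r2, cor(yhat, y)^2, tolerance = 1e-12)
  # trend-only variant equals the plain r2 of the trend predictions
  expect_equal(pseudo_r2(fit, y, X = X, trend_only = TRUE),
               cor(drop(cbind(1, X) %*% fit$beta), y)^2, tolerance = 1e-12)
})

test_that("AIC-based lag selection finds the generating band", {
  expect_equal(formals(select_lag)$lags, quote(candidate_lags()))
  set.seed(25)
  n <- 150
  xy <- matrix(runif(2 * n, 0, 600), ncol = 2)
  w100 <- build_distance_band_weights(xy, 100)
  X <- cbind(a = rnorm(n))
  y <- simulate_sar_response(X, 1, 0.7, 0.4, w100)

  single <- select_lag(y, X, xy, lags = 100)
  expect_equal(single$best_lag, 100)
  expect_equal(nrow(single$table), 1)

  hits <- 0L
  for (i in 1:10) {
    set.seed(500 + i)
    Xi <- cbind(a = rnorm(n))
    yi <- simulate_sar_response(Xi, 1, 0.7, 0.4, w100)
    sel <- select_lag(yi, Xi, xy, lags = c(50, 100, 400))
    hits <- hits + (sel$best_lag == 100)
  }
  expect_gte(hits, 6)
})

test_that("nested models never lose pseudo-r2 beyond tolerance", {
  set.seed(33)
  w <- grid_weights(12, 12, spacing = 50, lag_km = 60)
  n <- 144
  X_all <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("x", 1:5)))
  y <- simulate_sar_response(X_all[, 1:2], c(1, -0.6), 0.5, 0.5, w)
  cmp <- compare_full_model(y, X_all[, 1:2], X_all, w)
  expect_gte(cmp$delta_r2, -1e-8)
  cmp_same <- compare_full_model(y, X_all, X_all, w)
  expect_equal(cmp_same$delta_r2, 0, tolerance = 1e-12)
  expect_error(compare_full_model(y, cbind(zz = rnorm(n)), X_all, w),
               "subset")
})

test_that("area handling does not change the dominant predictor", {
  set.seed(55)
  n <- 300
  xy <- matrix(runif(2 * n, 0, 700), ncol = 2)
  w <- build_distance_band_weights(xy, 100)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  log_area <- rnorm(n, 3.2, 0.4)
  y <- simulate_sar_response(X, c(1.5, 0.2), 0.4, 0.3, w) + 0.5 * log_area
  res <- area_effect_check(y, X, log_area, w)
  expect_true(res$agree_top)
  expect_equal(res$ranking_residualized[1], "x1")
  expect_error(area_effect_check(y, X, rep(1, n), w), "constant")
})

test_that("the SAR report mirrors the standard table layout", {
  set.seed(3)
  w <- grid_weights(7, 7, spacing = 50, lag_km = 60)
  X <- cbind(a = rnorm(49))
  y <- simulate_sar_response(X, 2, 0.3, 0.3, w)
  rep <- sar_report(fit_sar_err(y, X, w))
  expect_named(rep$predictors, c("(Intercept)", "a"))
  expect_true(all(c("z", "stars") %in% names(rep$predictors$a)))
  expect_equal(rep$predictors$a$stars, "***")
  expect_true(all(c("aic", "pseudo_r2", "resid_moran", "lag_km") %in%
                    names(rep)))
})
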