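test_that("log transform respects per-variable flags", {
  expect_equal(log_transform(1000), 3)
  expect_equal(log_transform(1), 0)
  expect_error(log_transform(c(2, 0)), "non-positive")

  env <- toy_env(
    data.frame(min_temperature_coldest_month = c(-58.9, -10, 5),
               mean_annual_precipitation = c(100, 200, 400)),
    c(min_temperature_coldest_month = "ambient_energy",
      mean_annual_precipitation = "water_energy"),
    c(min_temperature_coldest_month = "none",
      mean_annual_precipitation = "log10"))
  out <- log_transform(env)
  expect_equal(out$values$min_temperature_coldest_month, c(-58.9, -10, 5))
  expect_equal(out$values$mean_annual_precipitation, log10(c(100, 200, 400)))
  expect_equal(out$transform[["min_temperature_coldest_month"]], "none")

  env$values$mean_annual_precipitation[2] <- -1
  expect_error(log_transform(env), "mean_annual_precipitation.*unit 2")
})

test_that("area residualization gives exact OLS residuals", {
  # hand OLS on y = (1,2,3), x = (1,2,4): slope 9/14, intercept 1/2
  r <- residualize_on_area(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r, c(-1 / 7, 3 / 14, -1 / 14), tolerance = 1e-12,
               ignore_attr = TRUE)

  # perfect linear relation -> zero residuals
  x <- c(0.5, 1.2, 2.5, 3.3)
  expect_equal(residualize_on_area(2 + 0.25 * x, x), rep(0, 4),
               tolerance = 1e-12, ignore_attr = TRUE)

  # normal equations: sum zero, orthogonal to the regressor
  set.seed(2)
  y <- rnorm(60); x <- rnorm(60)
  r <- residualize_on_area(y, x)
  expect_lt(abs(sum(r)), 1e-10)
  expect_lt(abs(sum(r * (x - mean(x)))), 1e-10)

  expect_error(residualize_on_area(y, rep(1, 60)), "constant")
})

test_that("Spearman matrix matches the rank-then-Pearson oracle", {
  set.seed(8)
  x <- rnorm(30)
  env <- toy_env(data.frame(a = x, b = x^3, c = -x, d = runif(30),
                            e = rnorm(30)),
                 c(a = "g1", b = "g1", c = "g1", d = "g1", e = "g2"))
  rho <- spearman_matrix(env, "g1")
  expect_equal(rho["a", "b"], 1)      # monotone invariance
  expect_equal(rho["a", "c"], -1)
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 4))
  # oracle: Pearson on average ranks
  oracle <- cor(apply(env$values[c("a", "b", "c", "d")], 2, rank))
  expect_equal(unname(rho), unname(oracle), tolerance = 1e-12)

  env$values$d <- 1  # constant: its pairs are NA
  rho2 <- spearman_matrix(env, "g1")
  expect_true(all(is.na(rho2["d", c("a", "b", "c")])))
  expect_error(spearman_matrix(env, "g2"), ">= 2 variables")
})

test_that("univariate deviance explained equals 1 - RSS/TSS", {
  x <- c(0.2, 0.9, 1.4, 2.2, 3.1, 4.0)
  expect_equal(univariate_deviance(2 * x + 1, x), 1)
  y <- c(1.1, 0.4, 2.2, 1.8, 3.5, 3.1)
  fit <- lm(y ~ x)
  expect_equal(univariate_deviance(y, x),
               1 - sum(resid(fit)^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_warning(d0 <- univariate_deviance(y, rep(2, 6)), "constant")
  expect_equal(d0, 0)
  set.seed(1)
  expect_lt(univariate_deviance(rnorm(2000), rnorm(2000)), 0.01)
})

test_that("screening drops the weaker member of correlated pairs", {
  set.seed(31)
  n <- 200
  y <- rnorm(n)
  x1 <- y + rnorm(n, 0, 0.8)          # strong predictor
  x2 <- x1 + rnorm(n, 0, 0.2)         # highly correlated, weaker copy
  x3 <- rnorm(n)                      # independent, same category
  x4 <- rnorm(n)                      # other category
  env <- toy_env(data.frame(x1 = x1, x2 = x2, x3 = x3, x4 = x4),
                 c(x1 = "g1", x2 = "g1", x3 = "g1", x4 = "g2"))
  stopifnot(cor(x1, x2, method = "spearman") > 0.7)
  stopifnot(univariate_deviance(y, x1) > univariate_deviance(y, x2))
  res <- screen_variables(env, y, threshold = 0.7)
  expect_setequal(res$retained$g1, c("x1", "x3"))
  expect_equal(res$retained$g2, "x4")
  expect_equal(res$dropped$dropped, "x2")
  expect_equal(res$dropped$kept, "x1")
  expect_gt(abs(res$dropped$rho), 0.7)
  expect_equal(res$threshold, 0.7)

  # everything below the threshold: all variables retained
  env2 <- toy_env(data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n)),
                  c(a = "g1", b = "g1", c = "g1"))
  res2 <- screen_variables(env2, y)
  expect_setequal(res2$retained$g1, c("a", "b", "c"))
  expect_equal(nrow(res2$dropped), 0)
})

test_that("screening is order-invariant and respects its invariant", {
  set.seed(77)
  n <- 80
  y <- rnorm(n)
  base <- matrix(rnorm(n * 6), n)
  vals <- as.data.frame(base)
  vals$V2 <- vals$V1 * 0.95 + rnorm(n, 0, 0.2)
  vals$V5 <- vals$V4 * 0.9 + rnorm(n, 0, 0.3)
  names(vals) <- paste0("v", 1:6)
  cats <- setNames(rep(c("g1", "g2"), each = 3), names(vals))
  env <- toy_env(vals, cats)
  res <- screen_variables(env, y)

  perm <- c(4, 2, 6, 1, 3, 5)
  env_p <- toy_env(vals[perm], cats[perm])
  res_p <- screen_variables(env_p, y)
  expect_setequal(retained_variables(res), retained_variables(res_p))

  # no retained within-category pair above the threshold
  for (ct in names(res$retained)) {
    kept <- res$retained[[ct]]
    if (length(kept) < 2) next
    rr <- abs(cor(vals[kept], method = "spearman"))
    diag(rr) <- 0
    expect_lte(max(rr), 0.7)
  }

  path <- withr::local_tempfile(fileext = ".json")
  write_screening_report(res, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$threshold, 0.7)
})
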