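# Shared fixtures and independent oracles used across the suite.

# Regular lattice weights: nx x ny grid at `spacing` km, band radius lag_km.
grid_weights <- function(nx, ny, spacing = 50, lag_km = 60) {
  xy <- expand.grid(x = (seq_len(nx) - 1) * spacing,
                    y = (seq_len(ny) - 1) * spacing)
  build_distance_band_weights(xy, lag_km)
}

# Naive O(n^2) Moran's I double sum.
naive_morans_i <- function(values, weights) {
  W <- as.matrix(weights$W)
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Dense-matrix SAR-error concentrated log-likelihood (direct determinant
# and solve; no eigenvalue shortcut).
dense_sar_loglik <- function(lambda, y, X, weights) {
  W <- as.matrix(weights$W)
  n <- length(y)
  A <- diag(n) - lambda * W
  ya <- A %*% y
  Xa <- A %*% X
  beta <- solve(crossprod(Xa), crossprod(Xa, ya))
  e <- ya - Xa %*% beta
  sigma2 <- sum(e^2) / n
  ld <- determinant(A, logarithm = TRUE)
  -(n / 2) * (log(2 * pi) + log(sigma2) + 1) + as.numeric(ld$modulus)
}

# Simulate a SAR-error response on given weights: y = X beta + u,
# u = (I - lambda W)^{-1} eps.
simulate_sar_response <- function(X, beta, lambda, sigma, weights,
                                  intercept = 0) {
  n <- nrow(X)
  eps <- rnorm(n, 0, sigma)
  u <- as.numeric(Matrix::solve(Matrix::Diagonal(n) - lambda * weights$W, eps))
  drop(intercept + X %*% beta + u)
}

# Small single-stratum generator configuration for fast tests.
small_config <- function(n_units = 120, region = "QTR", seed = 1,
                         ...) {
  generator_config(
    n_units = n_units,
    strata = list(stratum(region, c(0, 800, 0, 800), 1,
                          region_calibration(region))),
    seed = seed, ...)
}

# Generate a complete small landscape: counties, weights, env, richness.
small_landscape <- function(config) {
  counties <- generate_counties(config)
  weights <- build_distance_band_weights(counties[, c("x_km", "y_km")],
                                         config$spatial_range_km,
                                         ids = counties$id)
  env <- derive_variables(generate_env_fields(counties, config, weights))
  richness <- generate_richness(counties, env, weights, config)
  list(counties = counties, weights = weights, env = env,
       richness = richness)
}

# Build an env_matrix directly from a data.frame plus tag vectors.
toy_env <- function(values, category, transform = NULL) {
  if (is.null(transform))
    transform <- setNames(rep("none", length(category)), names(category))
  richscape:::new_env_matrix(values, category, transform)
}
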