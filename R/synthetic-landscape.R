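# ---------------------------------------------------------------------------
# Synthetic county landscapes: lattices of assessment units with spatially
# autocorrelated environmental fields calibrated to per-region means/SDs,
# log-scale richness with SAR-correlated error, and degraded survey
# inventories. Everything is deterministic given the configuration seed.
# ---------------------------------------------------------------------------

# Per-region calibration targets for the continuous environmental variables:
# means and SDs of each variable within the three macro-regions (eastern
# monsoon EMR, northwestern arid NAR, Qinghai-Tibetan plateau QTR).
# Temperatures are in 0.1 degC and may be negative; `positive` variables are
# generated log-normally so they stay strictly positive; `transform` is the
# scale used in analysis (log10 or none).
env_calibration_table <- function() {
  row <- function(variable, category, positive, transform, emr_m, emr_s,
                  nar_m, nar_s, qtr_m, qtr_s) {
    data.frame(variable = variable, category = category, positive = positive,
               transform = transform,
               region = c("EMR", "NAR", "QTR"),
               mean = c(emr_m, nar_m, qtr_m),
               sd = c(emr_s, nar_s, qtr_s))
  }
  do.call(rbind, list(
    row("mean_annual_precipitation", "water_energy", TRUE, "log10",
        1029.1, 448.9, 253.6, 136.6, 483.4, 249.3),
    row("precipitation_wettest_quarter", "water_energy", TRUE, "log10",
        522.7, 180.8, 158.8, 97.0, 293.0, 130.8),
    row("precipitation_driest_quarter", "water_energy", TRUE, "log10",
        70.4, 59.1, 9.1, 7.7, 11.0, 9.2),
    row("mean_annual_temperature", "ambient_energy", FALSE, "none",
        140.5, 49.6, 54.5, 32.3, 10.0, 35.7),
    row("max_temperature_warmest_month", "ambient_energy", FALSE, "none",
        299.5, 28.1, 274.9, 29.8, 162.8, 30.4),
    row("min_temperature_coldest_month", "ambient_energy", FALSE, "none",
        -34.9, 92.7, -189.8, 39.6, -178.5, 48.6),
    row("potential_evapotranspiration", "ambient_energy", TRUE, "log10",
        1091.4, 130.7, 952.1, 134.3, 767.1, 109.3),
    row("actual_evapotranspiration", "productivity", TRUE, "log10",
        780.5, 232.3, 258.8, 137.8, 485.9, 194.9),
    row("net_primary_productivity", "productivity", TRUE, "log10",
        488.6, 208.8, 129.1, 79.4, 225.3, 195.7),
    row("ndvi", "productivity", TRUE, "log10",
        527.6, 98.5, 303.8, 163.2, 346.0, 167.3),
    row("mean_diurnal_range", "environmental_stability", TRUE, "none",
        95.4, 20.0, 130.5, 10.6, 137.6, 14.8),
    row("temperature_seasonality", "environmental_stability", TRUE, "log10",
        8522.7, 2573.9, 11971.4, 1243.9, 7103.1, 1154.4),
    row("temperature_annual_range", "environmental_stability", TRUE, "none",
        334.4, 83.9, 464.7, 31.3, 341.3, 38.2),
    row("precipitation_seasonality", "environmental_stability", TRUE, "log10",
        78.7, 23.0, 90.6, 22.6, 100.5, 17.9),
    row("elevational_range", "habitat_heterogeneity", TRUE, "log10",
        1024.8, 812.1, 1884.0, 1533.8, 3060.8, 1211.3),
    row("mean_elevation", "habitat_heterogeneity", TRUE, "log10",
        541.7, 609.4, 1308.9, 515.4, 4029.8, 842.7),
    row("n_land_cover_types", "habitat_heterogeneity", TRUE, "log10",
        6.4, 2.1, 6.8, 2.4, 7.0, 2.2)
  ))
}

#' Calibration targets of one region
#'
#' Returns the per-variable generation targets (mean, SD, positivity flag,
#' hypothesis category, analysis transform) of one of the three built-in
#' macro-regions.
#'
#' @param region one of "EMR", "NAR", "QTR".
#' @return data.frame with columns variable, category, positive, transform,
#'   mean, sd.
#' @export
region_calibration <- function(region = c("EMR", "NAR", "QTR")) {
  region <- match.arg(region)
  tab <- env_calibration_table()
  out <- tab[tab$region == region,
             c("variable", "category", "positive", "transform", "mean", "sd")]
  rownames(out) <- NULL
  out
}

#' Define a stratum for the landscape generator
#'
#' @param label stratum name.
#' @param extent numeric c(xmin, xmax, ymin, ymax), planar km.
#' @param prop fraction of all units placed in this stratum.
#' @param env per-variable targets as returned by
#'   \code{\link{region_calibration}} (possibly edited).
#' @return a list usable in \code{generator_config(strata = ...)}.
#' @export
stratum <- function(label, extent, prop, env) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
            prop > 0)
  need <- c("variable", "mean", "sd", "positive", "category", "transform")
  if (!all(need %in% names(env))) stop("env must have columns: ",
                                       paste(need, collapse = ", "))
  list(label = label, extent = unname(extent), prop = prop, env = env)
}

# Three-region layout: a 4000 x 2400 km domain split so that the eastern
# monsoon, northwestern arid and plateau strata have realistic area shares
# (~47/29/24 %) and unit shares matching the 1995/210/171 county split.
default_strata <- function() {
  list(
    stratum("EMR", c(2140, 4000, 0, 2400), 1995 / 2376, region_calibration("EMR")),
    stratum("NAR", c(0, 2140, 1100, 2400), 210 / 2376, region_calibration("NAR")),
    stratum("QTR", c(0, 2140, 0, 1100), 171 / 2376, region_calibration("QTR"))
  )
}

default_cross_cor <- function() {
  list(
    list(source = "mean_annual_precipitation", target = "ndvi", rho = 0.77),
    list(source = "mean_annual_precipitation",
         target = "precipitation_wettest_quarter", rho = 0.90),
    list(source = "mean_annual_precipitation",
         target = "actual_evapotranspiration", rho = 0.75),
    list(source = "mean_annual_temperature",
         target = "min_temperature_coldest_month", rho = 0.80),
    list(source = "temperature_seasonality",
         target = "temperature_annual_range", rho = 0.85)
  )
}

# Effects on log10 richness (per unit of the analysis-scale covariate):
# habitat heterogeneity dominant, then productivity and water, a weak warm
# temperature effect (per 0.1 degC) and a weak land-cover code effect.
default_beta <- function() {
  c(elevational_range = 0.45,
    net_primary_productivity = 0.25,
    mean_annual_precipitation = 0.20,
    precipitation_seasonality = -0.15,
    max_temperature_warmest_month = 0.002,
    main_land_cover = -0.01)
}

#' Configuration of the synthetic landscape generator
#'
#' Collects every knob of the generating model: the county lattice (unit
#' count, strata with spatial extents and per-variable mean/SD targets, the
#' county-area lognormal), the environmental fields (spatial correlation via
#' an inverse SAR filter with coefficient \code{env_rho} on a distance band
#' of \code{spatial_range_km}, cross-correlations through shared latent
#' factors), and the richness response (log10 richness = intercept +
#' sum(beta * x) + gamma_area * log10(area) + SAR(lambda_true) error with
#' innovation SD \code{sigma}; optionally a hinge in one raw-scale variable).
#'
#' @param n_units number of assessment units (>= 10).
#' @param strata list of \code{\link{stratum}} objects.
#' @param spatial_range_km distance band (km) of the generator's internal
#'   weights; controls the correlation range of all fields.
#' @param env_rho SAR coefficient of the environmental fields, in (-1, 1).
#' @param lambda_true SAR coefficient of the richness error, in (-1, 1).
#' @param beta_true named vector of analysis-scale effects on log10 richness.
#' @param gamma_area effect of log10 area on log10 richness.
#' @param intercept intercept of the log10 richness predictor.
#' @param area_lognormal c(mean, sd) of county area in km^2.
#' @param breakpoint NULL, or list(variable, threshold, pre_slope,
#'   post_slope): replaces that variable's linear term with a two-slope hinge
#'   on the raw variable scale.
#' @param sigma innovation SD of the richness error (> 0).
#' @param cross_cor list of list(source, target, rho) latent correlations.
#' @param n_land_classes number of land-cover classes (integer codes).
#' @param seed integer master seed; all generator randomness derives from it.
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(n_units = 2376,
                             strata = default_strata(),
                             spatial_range_km = 100,
                             env_rho = 0.6,
                             lambda_true = 0.6,
                             beta_true = default_beta(),
                             gamma_area = 0.25,
                             intercept = -1.15,
                             area_lognormal = c(mean = 3908.7, sd = 9287.6),
                             breakpoint = NULL,
                             sigma = 0.15,
                             cross_cor = default_cross_cor(),
                             n_land_classes = 10,
                             seed = 1L) {
  if (!is.numeric(n_units) || n_units < 10) stop("n_units must be >= 10")
  if (!length(strata)) stop("at least one stratum required")
  if (sigma < 0) stop("sigma must be >= 0")
  if (abs(lambda_true) >= 1) stop("lambda_true must lie in (-1, 1)")
  if (abs(env_rho) >= 1) stop("env_rho must lie in (-1, 1)")
  if (spatial_range_km <= 0) stop("spatial_range_km must be positive")
  if (any(area_lognormal <= 0)) stop("area_lognormal mean/sd must be positive")
  gen_vars <- c(unique(unlist(lapply(strata, function(s) s$env$variable))),
                "main_land_cover", "mean_annual_dryness")
  bad <- setdiff(names(beta_true), gen_vars)
  if (length(bad)) stop("beta_true names not among generated covariates: ",
                        paste(bad, collapse = ", "))
  for (cc in cross_cor) {
    if (!all(c(cc$source, cc$target) %in% gen_vars))
      stop("cross_cor names unknown variable: ", cc$source, " / ", cc$target)
    if (abs(cc$rho) > 1) stop("cross_cor rho must be in [-1, 1]")
  }
  structure(list(n_units = as.integer(n_units), strata = strata,
                 spatial_range_km = spatial_range_km, env_rho = env_rho,
                 lambda_true = lambda_true, beta_true = beta_true,
                 gamma_area = gamma_area, intercept = intercept,
                 area_lognormal = area_lognormal, breakpoint = breakpoint,
                 sigma = sigma, cross_cor = cross_cor,
                 n_land_classes = as.integer(n_land_classes),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Deterministic child seeds so each generator stage has its own stream.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 104729) %% 2147483647)
}

#' Generate a county table
#'
#' Draws unit counts per stratum from the configured proportions, centroids
#' uniformly inside each stratum's extent, and areas from the lognormal
#' moment-matched to the configured mean/SD.
#'
#' @param config a \code{\link{generator_config}}.
#' @return data.frame (class \code{county_table}) with columns id, stratum,
#'   x_km, y_km, area_km2; attribute \code{seed}.
#' @export
generate_counties <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(child_seed(config$seed, 1L))
  props <- vapply(config$strata, `[[`, 0, "prop")
  props <- props / sum(props)
  n <- config$n_units
  counts <- diff(c(0L, round(cumsum(props) * n)))
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  if (any(counts < 1)) stop("a stratum received no units; adjust proportions")
  m <- config$area_lognormal[["mean"]]; s <- config$area_lognormal[["sd"]]
  sdlog <- sqrt(log(1 + (s / m)^2)); meanlog <- log(m) - sdlog^2 / 2
  rows <- lapply(seq_along(config$strata), function(i) {
    st <- config$strata[[i]]; k <- counts[i]
    data.frame(stratum = st$label,
               x_km = runif(k, st$extent[1], st$extent[2]),
               y_km = runif(k, st$extent[3], st$extent[4]),
               area_km2 = rlnorm(k, meanlog, sdlog))
  })
  out <- do.call(rbind, rows)
  out <- cbind(id = sprintf("u%05d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  attr(out, "seed") <- config$seed
  class(out) <- c("county_table", "data.frame")
  out
}

# Spatially autocorrelated standard field: inverse SAR filter applied to
# white noise, then standardized to mean 0 / SD 1 over the whole domain.
sar_field <- function(weights, rho) {
  n <- weights$n
  eps <- rnorm(n)
  if (rho == 0) z <- eps
  else z <- as.numeric(Matrix::solve(Matrix::Diagonal(n) - rho * weights$W, eps))
  as.numeric(scale(z))
}

#' Generate environmental covariate fields
#'
#' Each continuous variable is a spatially autocorrelated latent field
#' (inverse SAR filter at \code{env_rho} on \code{weights}); configured
#' cross-correlations are induced by mixing latent fields before rescaling.
#' Within each stratum the latent is standardized exactly and mapped to the
#' stratum's target moments: positive variables through a moment-matched
#' lognormal (so they remain strictly positive and the analysis log10 scale
#' is linear in the latent), signed variables affinely. A categorical main
#' land-cover code is produced by quantile-binning its own latent field, and
#' the land-cover-type count is rounded to an integer >= 1.
#'
#' @param counties a \code{county_table}.
#' @param config the \code{\link{generator_config}}.
#' @param weights \code{spatial_weights} built on the same units (typically
#'   at \code{config$spatial_range_km}).
#' @return an \code{env_matrix}: list(values, category, transform).
#' @export
generate_env_fields <- function(counties, config, weights) {
  stopifnot(inherits(config, "generator_config"))
  if (weights$n != nrow(counties)) stop("weights not built on these units")
  set.seed(child_seed(config$seed, 2L))
  meta <- config$strata[[1]]$env
  vars <- meta$variable
  latents <- matrix(0, nrow(counties), length(vars) + 1L,
                    dimnames = list(NULL, c(vars, "main_land_cover")))
  for (v in colnames(latents)) latents[, v] <- sar_field(weights, config$env_rho)
  for (cc in config$cross_cor) {
    if (!all(c(cc$source, cc$target) %in% colnames(latents)))
      stop("cross_cor refers to an ungenerated variable: ",
           cc$source, " / ", cc$target)
    latents[, cc$target] <- cc$rho * latents[, cc$source] +
      sqrt(1 - cc$rho^2) * latents[, cc$target]
  }
  values <- as.data.frame(matrix(NA_real_, nrow(counties), length(vars),
                                 dimnames = list(NULL, vars)))
  for (st in config$strata) {
    idx <- which(counties$stratum == st$label)
    if (!length(idx)) next
    for (j in seq_along(st$env$variable)) {
      v <- st$env$variable[j]
      z <- latents[idx, v]
      z <- if (length(idx) > 1 && sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
      m <- st$env$mean[j]; s <- st$env$sd[j]
      if (st$env$positive[j]) {
        sdlog <- sqrt(log(1 + (s / m)^2)); meanlog <- log(m) - sdlog^2 / 2
        values[idx, v] <- exp(meanlog + sdlog * z)
      } else {
        values[idx, v] <- m + s * z
      }
    }
  }
  if ("n_land_cover_types" %in% vars) {
    values$n_land_cover_types <- pmin(pmax(round(values$n_land_cover_types), 1),
                                      config$n_land_classes)
  }
  k <- config$n_land_classes
  lc <- latents[, "main_land_cover"]
  values$main_land_cover <- as.integer(cut(lc, breaks = quantile(
    lc, probs = seq(0, 1, length.out = k + 1)), include.lowest = TRUE))
  category <- c(stats::setNames(meta$category, meta$variable),
                main_land_cover = "habitat_heterogeneity")
  transform <- c(stats::setNames(meta$transform, meta$variable),
                 main_land_cover = "none")
  new_env_matrix(values, category, transform)
}

new_env_matrix <- function(values, category, transform) {
  stopifnot(identical(sort(names(values)), sort(names(category))),
            identical(sort(names(values)), sort(names(transform))))
  structure(list(values = values, category = category, transform = transform),
            class = "env_matrix")
}

#' @export
print.env_matrix <- function(x, ...) {
  cat(sprintf("env_matrix: %d units x %d variables\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$category))
  invisible(x)
}

#' Variables of an environment matrix
#' @param env an \code{env_matrix}.
#' @return character vector of variable names.
#' @export
env_variables <- function(env) names(env$values)

#' Derive the dryness index
#'
#' Adds mean annual dryness = mean annual precipitation / annual potential
#' evapotranspiration (dimensionless) as a water-energy variable; inputs are
#' left unchanged.
#'
#' @param env an \code{env_matrix} containing \code{mean_annual_precipitation}
#'   and \code{potential_evapotranspiration} (all PET values must be > 0).
#' @return the augmented \code{env_matrix}.
#' @export
derive_variables <- function(env) {
  stopifnot(inherits(env, "env_matrix"))
  need <- c("mean_annual_precipitation", "potential_evapotranspiration")
  if (!all(need %in% names(env$values)))
    stop("precipitation and potential-evapotranspiration columns required")
  pet <- env$values$potential_evapotranspiration
  if (any(pet <= 0)) stop("potential evapotranspiration must be > 0 everywhere")
  env$values$mean_annual_dryness <- env$values$mean_annual_precipitation / pet
  env$category <- c(env$category, mean_annual_dryness = "water_energy")
  env$transform <- c(env$transform, mean_annual_dryness = "log10")
  env
}

#' Generate a richness response
#'
#' log10 richness = intercept + sum_k beta_k x_k (x on the analysis scale) +
#' gamma_area * log10(area) + u, with u = lambda W u + eps and eps iid
#' N(0, sigma^2). If a breakpoint is configured, the linear term of that
#' variable is replaced by a two-slope hinge on its raw scale:
#' pre_slope * min(x, threshold) + post_slope * max(x - threshold, 0).
#' The result is back-transformed (10^) and rounded to an integer >= 1.
#'
#' @param counties a \code{county_table}.
#' @param env an \code{env_matrix} containing every \code{beta_true} variable.
#' @param weights \code{spatial_weights} on the same units.
#' @param config the \code{\link{generator_config}}.
#' @return integer vector of richness values (>= 1); attribute
#'   \code{log10_expected} carries the noise-free linear predictor.
#' @export
generate_richness <- function(counties, env, weights, config) {
  stopifnot(inherits(config, "generator_config"), inherits(env, "env_matrix"))
  if (abs(config$lambda_true) >= 1)
    stop("lambda_true must lie in (-1, 1) for a stationary error process")
  missing_vars <- setdiff(names(config$beta_true), names(env$values))
  if (length(missing_vars))
    stop("beta_true variables absent from env: ",
         paste(missing_vars, collapse = ", "))
  set.seed(child_seed(config$seed, 3L))
  n <- nrow(counties)
  lp <- rep(config$intercept, n) +
    config$gamma_area * log10(counties$area_km2)
  bp <- config$breakpoint
  for (v in names(config$beta_true)) {
    if (!is.null(bp) && identical(v, bp$variable)) next
    x <- env$values[[v]]
    if (env$transform[[v]] == "log10") {
      if (any(x <= 0)) stop("non-positive value in log10 variable ", v)
      x <- log10(x)
    }
    lp <- lp + config$beta_true[[v]] * x
  }
  if (!is.null(bp)) {
    xr <- env$values[[bp$variable]]
    lp <- lp + bp$pre_slope * pmin(xr, bp$threshold) +
      bp$post_slope * pmax(xr - bp$threshold, 0)
  }
  u <- if (config$sigma == 0) rep(0, n) else {
    eps <- rnorm(n, 0, config$sigma)
    as.numeric(Matrix::solve(Matrix::Diagonal(n) -
                               config$lambda_true * weights$W, eps))
  }
  richness <- pmax(1L, as.integer(round(10^(lp + u))))
  attr(richness, "log10_expected") <- lp
  richness
}

#' Degrade an inventory by binomial thinning
#'
#' Each unit's observed richness is a Binomial(richness, 1 - omission) draw;
#' the per-unit incompleteness score is 1 - observed/true, which is zero at
#' omission zero and increases (in expectation) with the omission rate.
#'
#' @param richness integer vector of true richness.
#' @param omission_rates per-unit omission probabilities in \[0, 1\]
#'   (recycled if scalar).
#' @param seed integer seed.
#' @return list(observed, incompleteness).
#' @export
degrade_survey <- function(richness, omission_rates, seed = 1L) {
  omission_rates <- rep_len(omission_rates, length(richness))
  if (any(omission_rates < 0 | omission_rates > 1))
    stop("omission rates must lie in [0, 1]")
  set.seed(as.integer(seed))
  observed <- rbinom(length(richness), size = richness,
                     prob = 1 - omission_rates)
  list(observed = observed,
       incompleteness = 1 - observed / pmax(richness, 1L))
}

#' Generate a pixel raster consistent with county-level fields
#'
#' A small per-county pixel grid used to exercise zonal statistics: pixel
#' elevations are uniform over [mean_elevation - range/2, + range/2] (clipped
#' at zero) and land-cover classes are drawn so the county's configured main
#' class is the modal one.
#'
#' @param counties a \code{county_table}.
#' @param env an \code{env_matrix} with mean_elevation, elevational_range and
#'   main_land_cover.
#' @param pixels_per_county pixels per unit (>= 1).
#' @param n_land_classes number of land-cover classes.
#' @param seed integer seed.
#' @return data.frame with columns county, elevation, land_cover.
#' @export
generate_pixel_raster <- function(counties, env, pixels_per_county = 16,
                                  n_land_classes = 10, seed = 1L) {
  stopifnot(pixels_per_county >= 1)
  set.seed(as.integer(seed))
  n <- nrow(counties)
  rows <- lapply(seq_len(n), function(i) {
    me <- env$values$mean_elevation[i]; er <- env$values$elevational_range[i]
    elev <- pmax(0, runif(pixels_per_county, me - er / 2, me + er / 2))
    main <- env$values$main_land_cover[i]
    lc <- ifelse(runif(pixels_per_county) < 0.6, main,
                 sample.int(n_land_classes, pixels_per_county, replace = TRUE))
    data.frame(county = counties$id[i], elevation = elev, land_cover = lc)
  })
  do.call(rbind, rows)
}

#' Zonal aggregation of pixel values to counties
#'
#' @param raster data.frame with a \code{county} column and the value column.
#' @param column name of the pixel value column.
#' @param statistic "mean" (pixel average), "range" (max - min) or
#'   "majority" (modal class; ties broken by the smallest class code).
#' @param county_ids optional vector of counties that must all be present;
#'   a county with zero pixels raises an error naming it.
#' @return named numeric vector, one value per county.
#' @export
zonal_aggregate <- function(raster, column, statistic = c("mean", "range",
                                                          "majority"),
                            county_ids = NULL) {
  statistic <- match.arg(statistic)
  if (!all(c("county", column) %in% names(raster)))
    stop("raster must have columns 'county' and '", column, "'")
  if (!is.null(county_ids)) {
    missing_c <- setdiff(as.character(county_ids),
                         as.character(unique(raster$county)))
    if (length(missing_c))
      stop("county with zero pixels: ", paste(missing_c, collapse = ", "))
  }
  f <- switch(statistic,
              mean = function(v) mean(v),
              range = function(v) max(v) - min(v),
              majority = function(v) {
                tab <- table(v)
                as.numeric(names(tab)[which.max(tab)])
              })
  out <- tapply(raster[[column]], raster$county, f)
  res <- stats::setNames(as.numeric(out), names(out))
  if (!is.null(county_ids)) res <- res[as.character(county_ids)]
  res
}

#' Write the county table and environment matrix as delimited text
#'
#' One row per unit; header comment lines record the master seed and the
#' per-variable hypothesis category and analysis transform.
#'
#' @param counties a \code{county_table}.
#' @param env an \code{env_matrix} on the same units (optional).
#' @param path output file (tab-separated).
#' @param richness optional named list of richness vectors to append as
#'   columns (e.g. list(plants = ..., mammals = ...)).
#' @return \code{path}, invisibly.
#' @export
write_county_table <- function(counties, env = NULL, path,
                               richness = NULL) {
  df <- as.data.frame(counties)
  hdr <- sprintf("# seed=%s", attr(counties, "seed"))
  if (!is.null(env)) {
    df <- cbind(df, env$values)
    hdr <- c(hdr,
             sprintf("# variable=%s category=%s transform=%s",
                     names(env$values), env$category[names(env$values)],
                     env$transform[names(env$values)]))
  }
  if (!is.null(richness))
    for (nm in names(richness)) df[[paste0("richness_", nm)]] <- richness[[nm]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generator configuration as JSON
#' @param config a \code{\link{generator_config}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_generator_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$strata <- lapply(cfg$strata, function(s) {
    s$env <- as.list(s$env); s
  })
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
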