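test_that("county generation honours strata, areas and the seed contract", {
  cfg10 <- small_config(n_units = 10)
  co10 <- generate_counties(cfg10)
  expect_equal(nrow(co10), 10)
  expect_true(all(co10$stratum == "QTR"))
  st <- cfg10$strata[[1]]
  expect_true(all(co10$x_km >= st$extent[1] & co10$x_km <= st$extent[2]))
  expect_true(all(co10$y_km >= st$extent[3] & co10$y_km <= st$extent[4]))

  # identical config twice -> identical tables
  expect_identical(generate_counties(cfg10), co10)

  # area lognormal calibrated to mean 3908.7, SD 9287.6: the sample mean is
  # stable at n=2000; the sample SD of so heavy-tailed a lognormal is not, so
  # the SD calibration is checked on the log scale where moments are exact
  cfg <- generator_config(n_units = 2000, seed = 3)
  co <- generate_counties(cfg)
  expect_lt(abs(mean(co$area_km2) - 3908.7) / 3908.7, 0.15)
  sdlog <- sqrt(log(1 + (9287.6 / 3908.7)^2))
  meanlog <- log(3908.7) - sdlog^2 / 2
  expect_lt(abs(mean(log(co$area_km2)) - meanlog), 3 * sdlog / sqrt(2000))
  expect_lt(abs(sd(log(co$area_km2)) - sdlog) / sdlog, 0.05)

  expect_error(generator_config(n_units = 5), "n_units")
  expect_error(stratum("bad", c(0, -10, 0, 10), 1, region_calibration("EMR")))
})

test_that("environmental fields hit stratum moments and cross-correlations", {
  cfg <- small_config(n_units = 500, region = "QTR", seed = 9)
  land <- small_landscape(cfg)
  er <- land$env$values$elevational_range
  expect_lt(abs(mean(er) - 3060.8) / 3060.8, 0.10)
  expect_lt(abs(sd(er) - 1211.3) / 1211.3, 0.10)
  expect_true(all(er > 0))

  # NAR-like stratum: NDVI vs precipitation latent correlation 0.77
  cfgn <- small_config(n_units = 400, region = "NAR", seed = 2)
  landn <- small_landscape(cfgn)
  r <- cor(log10(landn$env$values$mean_annual_precipitation),
           log10(landn$env$values$ndvi))
  expect_lt(abs(r - 0.77), 0.1)

  # category tags follow the five hypotheses
  expect_setequal(unique(unname(land$env$category)),
                  c("water_energy", "ambient_energy", "productivity",
                    "environmental_stability", "habitat_heterogeneity"))

  expect_error(
    generator_config(cross_cor = list(list(source = "nope", target = "ndvi",
                                           rho = 0.5))),
    "unknown")
})

test_that("rho = 0 fields show no spatial autocorrelation", {
  cfg <- small_config(n_units = 150, env_rho = 0, seed = 13)
  land <- small_landscape(cfg)
  res <- morans_i(log10(land$env$values$net_primary_productivity),
                  land$weights, nperm = 999)
  expect_gt(res$p_value, 0.05)
})

test_that("zonal aggregation computes mean, range and majority", {
  r <- data.frame(county = c("a", "a", "a", "b", "b", "b", "c", "c", "c", "c"),
                  elevation = c(100, 500, 2600, 10, 20, 30, 1, 2, 3, 4),
                  land_cover = c(1, 1, 2, 3, 3, 3, 4, 4, 5, 6))
  expect_equal(unname(zonal_aggregate(r, "elevation", "range")["a"]), 2500)
  expect_equal(unname(zonal_aggregate(r, "land_cover", "majority")["a"]), 1)
  expect_equal(unname(zonal_aggregate(r, "elevation", "mean")["c"]), 2.5)
  expect_error(zonal_aggregate(r, "elevation", "mean",
                               county_ids = c("a", "zzz")),
               "zzz")
})

test_that("pixel rasters aggregate back to county-level fields", {
  cfg <- small_config(n_units = 30, seed = 5)
  land <- small_landscape(cfg)
  px <- generate_pixel_raster(land$counties, land$env,
                              pixels_per_county = 200, seed = 8)
  rng <- zonal_aggregate(px, "elevation", "range",
                         county_ids = land$counties$id)
  # pixel range under-estimates the county range but tracks it
  expect_gt(cor(rng, land$env$values$elevational_range), 0.9)
  maj <- zonal_aggregate(px, "land_cover", "majority",
                         county_ids = land$counties$id)
  expect_gt(mean(maj == land$env$values$main_land_cover), 0.9)
})

test_that("dryness is precipitation over potential evapotranspiration", {
  env <- toy_env(
    data.frame(mean_annual_precipitation = c(921.3, 0, 500),
               potential_evapotranspiration = c(1055.8, 800, 500)),
    c(mean_annual_precipitation = "water_energy",
      potential_evapotranspiration = "ambient_energy"))
  out <- derive_variables(env)
  expect_equal(out$values$mean_annual_dryness, c(921.3 / 1055.8, 0, 1))
  expect_equal(out$values$mean_annual_dryness[1], 0.8726, tolerance = 1e-4)
  # inputs unchanged
  expect_equal(out$values$mean_annual_precipitation,
               env$values$mean_annual_precipitation)

  env$values$potential_evapotranspiration[2] <- 0
  expect_error(derive_variables(env), "> 0")
})

test_that("richness follows the configured generating model", {
  # beta = 0, gamma = 0, sigma = 0, intercept = 2: closed form 10^2 = 100
  cfg <- small_config(n_units = 40, seed = 6, beta_true = c(ndvi = 0),
                      gamma_area = 0, sigma = 0, intercept = 2)
  land <- small_landscape(cfg)
  expect_true(all(land$richness == 100L))

  # default calibration: max county richness of order 3e3
  big <- generator_config(seed = 7)
  landb <- small_landscape(big)
  expect_gt(max(landb$richness), 1000)
  expect_lt(max(landb$richness), 10000)
  expect_gte(min(landb$richness), 1)

  # determinism
  expect_identical(small_landscape(cfg)$richness, land$richness)

  expect_error(generator_config(lambda_true = 1), "lambda_true")
  expect_error(generator_config(beta_true = c(not_a_var = 1)), "not_a_var")
})

test_that("a generated hinge is recovered by the split-line module", {
  cfg <- small_config(
    n_units = 400, region = "EMR", seed = 10, sigma = 0, gamma_area = 0,
    intercept = 1.5, beta_true = c(elevational_range = 0),
    breakpoint = list(variable = "elevational_range", threshold = 1900,
                      pre_slope = 4e-4, post_slope = 0))
  land <- small_landscape(cfg)
  fit <- fit_split_line(land$env$values$elevational_range,
                        log10(land$richness),
                        grid = seq(500, 5000, by = 50))
  # integer rounding of richness is the only noise; one grid step of slack
  expect_lte(abs(fit$breakpoint - 1900), 50)
  expect_lt(abs(fit$post$slope), 1e-5)
})

test_that("survey degradation is binomial thinning with monotone scores", {
  rich <- rep(1000L, 50)
  none <- degrade_survey(rich, 0, seed = 1)
  expect_identical(none$observed, rich)
  expect_true(all(none$incompleteness == 0))

  half <- degrade_survey(rich, 0.5, seed = 2)
  sd3 <- 3 * sqrt(1000 * 0.25)
  expect_true(all(abs(half$observed - 500) < sd3))
  expect_gt(mean(half$incompleteness), mean(none$incompleteness))

  expect_identical(degrade_survey(rich, 0.3, seed = 7),
                   degrade_survey(rich, 0.3, seed = 7))
  expect_error(degrade_survey(rich, 1.2), "0, 1")
})

test_that("county table and config serialize to text with tagged headers", {
  cfg <- small_config(n_units = 25, seed = 4)
  land <- small_landscape(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_county_table(land$counties, land$env, path,
                     richness = list(plants = land$richness))
  lines <- readLines(path)
  expect_match(lines[1], "^# seed=")
  expect_true(any(grepl("variable=elevational_range category=habitat_heterogeneity",
                        lines)))
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(df), 25)
  expect_true("richness_plants" %in% names(df))

  cpath <- withr::local_tempfile(fileext = ".json")
  write_generator_config(cfg, cpath)
  cfg_back <- jsonlite::read_json(cpath)
  expect_equal(cfg_back$n_units, 25)
})
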