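# ---------------------------------------------------------------------------
# Orchestration: generate -> screen -> select -> fit -> diagnose, per taxon
# and per region, with JSON-first reporting.
# ---------------------------------------------------------------------------

#' Pipeline run configuration
#'
#' @param generator a \code{\link{generator_config}} describing the synthetic
#'   landscape (its seed is overridden by \code{seed}).
#' @param taxa named list; each element is NULL (use the generator's richness
#'   settings as-is) or a list of overrides (\code{beta_true}, \code{sigma},
#'   \code{intercept}, \code{breakpoint}, ...) applied for that taxon. Each
#'   taxon gets its own derived seed.
#' @param regions regions to analyse; NULL = the whole domain ("all") plus
#'   each stratum.
#' @param lags candidate lag distances (km) for the SAR weights.
#' @param reps bootstrap replicates in the selection and robustness stages.
#' @param alpha significance level.
#' @param k number of predictors selected.
#' @param threshold Spearman screening threshold.
#' @param fractions robustness subsample fractions.
#' @param splitline_variable raw-scale variable for the split-line analysis.
#' @param splitline_cap x-cap for the split-line analysis (default 6000).
#' @param hotspot_quantile richest fraction flagged as hotspots (default 0.05).
#' @param omission_rates per-unit omission used to fabricate the degraded
#'   reference survey for the completeness audit (scalar or vector).
#' @param seed master seed of the whole run.
#' @param output_dir NULL, or a directory where the JSON report and
#'   delimited-text mirrors are written.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(generator = generator_config(),
                       taxa = list(plants = NULL),
                       regions = NULL,
                       lags = candidate_lags(),
                       reps = 1000, alpha = 0.05, k = 6,
                       threshold = 0.7,
                       fractions = c(0.6, 0.7, 0.8, 0.9),
                       splitline_variable = "elevational_range",
                       splitline_cap = 6000,
                       hotspot_quantile = 0.05,
                       omission_rates = 0.15,
                       seed = 1L,
                       output_dir = NULL) {
  stopifnot(inherits(generator, "generator_config"), length(taxa) >= 1)
  if (is.null(names(taxa)) || any(names(taxa) == ""))
    stop("taxa must be a named list")
  structure(list(generator = generator, taxa = taxa, regions = regions,
                 lags = lags, reps = reps, alpha = alpha, k = k,
                 threshold = threshold, fractions = fractions,
                 splitline_variable = splitline_variable,
                 splitline_cap = splitline_cap,
                 hotspot_quantile = hotspot_quantile,
                 omission_rates = omission_rates,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Identify richness hotspots
#'
#' Units at or above the (1 - quantile) empirical quantile of richness; ties
#' at the cutoff are all included (and flagged).
#'
#' @param richness numeric vector.
#' @param quantile richest fraction (default 0.05).
#' @param ids optional unit ids (default positions).
#' @return vector of hotspot ids, with attributes \code{cutoff} and
#'   \code{tied} (TRUE when cutoff ties inflated the set).
#' @export
identify_hotspots <- function(richness, quantile = 0.05, ids = NULL) {
  if (!length(richness)) stop("empty richness vector")
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  if (is.null(ids)) ids <- seq_along(richness)
  cut <- stats::quantile(richness, 1 - quantile, names = FALSE, type = 7)
  sel <- which(richness >= cut)
  tied <- length(sel) > ceiling(quantile * length(richness))
  if (tied) warning("ties at the hotspot cutoff: ", length(sel),
                    " units returned")
  structure(ids[sel], cutoff = cut, tied = tied)
}

# Analysis-scale design matrix for a set of variables.
analysis_matrix <- function(env, vars, rows = NULL) {
  av <- log_transform(env)$values
  if (is.null(rows)) rows <- seq_len(nrow(av))
  as.matrix(av[rows, vars, drop = FALSE])
}

# Drop columns that make the (intercept-augmented) design rank deficient,
# keeping `protect` columns. In the synthetic world the derived dryness is an
# exact log-linear combination of precipitation and PET, so the all-variable
# model needs this guard.
drop_collinear <- function(X, protect = character()) {
  Xd <- cbind(1, X)
  qrx <- qr(Xd)
  if (qrx$rank == ncol(Xd)) return(X)
  ord <- c(protect, setdiff(colnames(X), protect))
  keep <- character()
  for (v in ord) {
    cand <- cbind(1, X[, c(keep, v), drop = FALSE])
    if (qr(cand)$rank == ncol(cand)) keep <- c(keep, v)
  }
  X[, colnames(X)[colnames(X) %in% keep], drop = FALSE]
}

# One taxon x region analysis cell; errors are caught by the caller.
analyze_cell <- function(counties, env, richness, region, cfg, taxon_seed) {
  rows <- if (identical(region, "all")) seq_len(nrow(counties))
  else which(counties$stratum == region)
  if (length(rows) < 20) stop("region '", region, "' has too few units")
  sub_counties <- counties[rows, , drop = FALSE]
  rich <- richness[rows]

  log_rich <- log_transform(as.numeric(rich))
  log_area <- log_transform(sub_counties$area_km2)
  y_resid <- residualize_on_area(log_rich, log_area)

  sub_env <- new_env_matrix(env$values[rows, , drop = FALSE],
                            env$category, env$transform)
  screening <- screen_variables(sub_env, y_resid, threshold = cfg$threshold)
  screened_vars <- retained_variables(screening)

  X_screened <- analysis_matrix(sub_env, screened_vars)
  sel_report <- bootstrap_significance(y_resid, X_screened, reps = cfg$reps,
                                       alpha = cfg$alpha,
                                       seed = child_seed(taxon_seed, 11L))
  top_vars <- select_top_k(sel_report, cfg$k)

  X_top <- analysis_matrix(sub_env, as.character(top_vars))
  lag_sel <- select_lag(y_resid, X_top,
                        sub_counties[, c("x_km", "y_km")], lags = cfg$lags)
  fit <- lag_sel$fit

  X_all <- drop_collinear(analysis_matrix(sub_env, env_variables(sub_env)),
                          protect = as.character(top_vars))
  cmp <- tryCatch(
    compare_full_model(y_resid, X_top, X_all, lag_sel$weights),
    error = function(e) list(delta_r2 = NA_real_, aic_top = fit$aic,
                             aic_all = NA_real_, error = conditionMessage(e)))

  split <- tryCatch({
    sl <- fit_split_line(sub_env$values[[cfg$splitline_variable]],
                         log_rich, x_cap = cfg$splitline_cap)
    split_line_report(sl)
  }, error = function(e) list(error = conditionMessage(e)))

  robust <- robustness_test(y_resid, X_screened, sub_counties,
                            fractions = cfg$fractions, reps = cfg$reps,
                            alpha = cfg$alpha, k = cfg$k,
                            seed = child_seed(taxon_seed, 13L))

  hots <- identify_hotspots(rich, cfg$hotspot_quantile, ids = sub_counties$id)

  list(
    region = region, n = length(rows),
    screening = list(threshold = screening$threshold,
                     retained = screening$retained,
                     n_dropped = nrow(screening$dropped)),
    selection = list(counts = as.list(sel_report$counts),
                     selected = as.character(top_vars),
                     reps = cfg$reps, alpha = cfg$alpha),
    sar = c(sar_report(fit),
            list(lag_table = lag_sel$table, best_lag = lag_sel$best_lag)),
    full_model_comparison = list(delta_r2 = cmp$delta_r2,
                                 aic_top = cmp$aic_top,
                                 aic_all = cmp$aic_all),
    split_line = split,
    robustness = list(fractions = robust$fractions,
                      top_k = robust$top_k,
                      full_top_k = robust$full_top_k,
                      consistent = robust$consistent),
    hotspots = list(ids = as.character(hots),
                    cutoff = attr(hots, "cutoff"),
                    n = length(hots))
  )
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic landscape (counties, environmental fields,
#' richness per taxon, a degraded reference survey), then for every taxon and
#' region runs: screening, area residualization, bootstrap top-k selection,
#' SAR error fit at the AIC-selected lag (z ranking, AIC, pseudo-r2, residual
#' Moran's I), the all-variable comparison (delta-r2), the split-line fit,
#' the stratified-subsampling robustness test, and the hotspot and
#' completeness audits. A failing region/taxon cell is reported as a
#' structured error without aborting the run.
#'
#' @param config a \code{\link{run_config}}.
#' @return the report bundle (nested list); written as JSON (plus text
#'   mirrors) under \code{config$output_dir} when that is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  gen <- config$generator
  gen$seed <- child_seed(config$seed, 1L)

  counties <- generate_counties(gen)
  gen_weights <- build_distance_band_weights(counties[, c("x_km", "y_km")],
                                             gen$spatial_range_km,
                                             ids = counties$id)
  env <- derive_variables(generate_env_fields(counties, gen, gen_weights))

  regions <- config$regions
  if (is.null(regions)) regions <- c("all", unique(counties$stratum))

  report <- list(seed = config$seed, n_units = nrow(counties),
                 regions = regions, taxa = list())
  for (ti in seq_along(config$taxa)) {
    taxon <- names(config$taxa)[ti]
    taxon_seed <- child_seed(config$seed, 1000L + ti)
    tg <- gen
    overrides <- config$taxa[[ti]]
    if (!is.null(overrides)) tg[names(overrides)] <- overrides
    tg$seed <- taxon_seed
    richness <- generate_richness(counties, env, gen_weights, tg)

    survey <- degrade_survey(richness, config$omission_rates,
                             seed = child_seed(taxon_seed, 21L))
    completeness <- compare_inventories(
      stats::setNames(as.numeric(richness), counties$id),
      stats::setNames(as.numeric(survey$observed), counties$id),
      stats::setNames(survey$incompleteness, counties$id))
    n_res <- min(217L, nrow(counties))
    set.seed(child_seed(taxon_seed, 22L))
    res_idx <- sort(sample.int(nrow(counties), n_res))
    reserve <- degrade_survey(richness[res_idx], 0.2,
                              seed = child_seed(taxon_seed, 23L))
    nested <- nested_reserve_correlation(as.numeric(richness[res_idx]),
                                         as.numeric(reserve$observed))

    cells <- list()
    for (region in regions) {
      cells[[region]] <- tryCatch(
        analyze_cell(counties, env, richness, region, config, taxon_seed),
        error = function(e) list(region = region,
                                 error = conditionMessage(e)))
    }
    report$taxa[[taxon]] <- list(
      richness_summary = list(max = max(richness),
                              median = stats::median(richness),
                              min = min(richness)),
      completeness = unclass(completeness),
      nested_reserve = nested,
      regions = cells)
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_county_table(counties, env,
                       file.path(config$output_dir, "counties.tsv"))
    message("report written to ", config$output_dir)
  }
  report
}
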