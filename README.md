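# richscape

Tools for disentangling the environmental determinants of species richness
recorded on county-like assessment units, for macroecologists and
conservation analysts working with richness inventories and gridded
environmental covariates.

Richness on contiguous units is spatially autocorrelated, so the package is
built around the simultaneous autoregressive (SAR) **error** model

    y = X beta + u,    u = lambda W u + eps,    eps ~ N(0, sigma^2 I)

fitted by maximum likelihood: with A = I − lambda W, the concentrated
log-likelihood

    l(lambda) = −(n/2) (log 2*pi + log sigma2_hat(lambda) + 1) + log |A|

is maximized over lambda, with beta_hat = (X'A'AX)^{-1} X'A'A y,
sigma2_hat = e'A'Ae / n, and log|A| = sum_i log(1 − lambda e_i) from the
eigenvalues e_i of the row-standardized distance-band weights matrix W.
Predictors are ranked by z = beta/SE; models are compared by AIC,
pseudo-r² (squared Pearson correlation of observed values with
X beta_hat + lambda_hat W (y − X beta_hat)) and residual Moran's I.

Around that core the package implements the full analysis chain:

* **`synthetic landscape`** — `generator_config()`, `generate_counties()`,
  `generate_env_fields()`, `generate_richness()`, `degrade_survey()`:
  county lattices in three region-like strata, spatially autocorrelated
  covariate fields calibrated to per-region means/SDs for the five
  hypothesis families (water-energy, ambient energy, productivity,
  environmental stability, habitat heterogeneity), log-scale richness with
  SAR error, and binomially thinned survey inventories.
* **Step 1, screening** — `log_transform()`, `residualize_on_area()`,
  `spearman_matrix()`, `screen_variables()`: remove the county-area effect,
  then within each hypothesis category drop the weaker member of every pair
  with Spearman |rho| > 0.7.
* **Step 2, selection** — `fit_glm()`, `bootstrap_significance()`,
  `select_top_k()`: Gaussian GLMs on 1000 bootstrap resamples, variables
  ranked by how often their coefficient reaches p < 0.05, top six kept.
* **Step 3, spatial model** — `build_distance_band_weights()`,
  `select_lag()`, `fit_sar_err()`, `compare_full_model()`,
  `area_effect_check()`: SAR error fits at candidate lags (50–1000 km), lag
  chosen by minimum AIC, delta-r² against the all-variable model.
* **Breakpoint analysis** — `fit_split_line()`: two-segment split-line
  regression of richness on elevational range with a grid-searched
  breakpoint (units above 6000 m of relief excluded).
* **Audits** — `stratified_sample()`, `robustness_test()` (top-6 stability
  under 60–90% stratified subsampling), `compare_inventories()` and
  `nested_reserve_correlation()` (inventory completeness),
  `identify_hotspots()` (richest 5%).
* **Pipeline** — `run_config()` / `run_pipeline()` orchestrate everything
  per taxon and region with JSON reports; `inst/cli/richscape` is a thin
  command-line front end with `generate`, `screen`, `select`, `sar`,
  `splitline`, `robustness`, `completeness`, `hotspots` and `run`
  subcommands.

## Worked example

Generate a 500-county landscape at the default calibration (elevational
range the dominant effect, lambda = 0.6 on a 100 km band), then run the
three steps:

```r
library(richscape)
cfg      <- generator_config(n_units = 500, seed = 1)
counties <- generate_counties(cfg)
w        <- build_distance_band_weights(counties[, c("x_km", "y_km")], 100,
                                        ids = counties$id)
env      <- derive_variables(generate_env_fields(counties, cfg, w))
richness <- generate_richness(counties, env, w, cfg)

y   <- residualize_on_area(log_transform(as.numeric(richness)),
                           log_transform(counties$area_km2))
scr <- screen_variables(env, y)
X   <- as.matrix(log_transform(env)$values[retained_variables(scr)])
top <- select_top_k(bootstrap_significance(y, X, reps = 500, seed = 1), 6)
fit <- select_lag(y, as.matrix(log_transform(env)$values[as.character(top)]),
                  counties[, c("x_km", "y_km")])$fit
fit
```

```
SAR error model: n = 500, lag = 100 km
  lambda = 0.6246  logLik = 211.94  AIC = -405.9  pseudo-r2 = 0.713  residual Moran's I = 0.010
                                 beta     se        z      p sig
(Intercept)                   -3.2723 0.2148 -15.2324 0.0000 ***
elevational_range              0.4951 0.0287  17.2795 0.0000 ***
max_temperature_warmest_month  0.0020 0.0002   9.7969 0.0000 ***
net_primary_productivity       0.2197 0.0366   6.0110 0.0000 ***
mean_annual_precipitation      0.2568 0.0371   6.9167 0.0000 ***
precipitation_seasonality     -0.0102 0.0746  -0.1367 0.8912    
main_land_cover               -0.0080 0.0030  -2.6512 0.0080  **
```

Reading the output: the bootstrap top-6 are exactly the six variables the
generator used; the AIC-selected lag (100 km) is the generating correlation
range; `lambda = 0.62` recovers the generating spatial error coefficient
0.6; elevational range attains the largest z, i.e. habitat heterogeneity is
correctly identified as the dominant determinant; and the residual Moran's
I near 0 shows the spatial error term absorbed the autocorrelation.

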