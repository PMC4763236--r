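Package: richscape
Title: Spatial Determinants of Species Richness Across County Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for disentangling the environmental
    determinants of species richness recorded on county-like assessment
    units. Provides a synthetic landscape generator (spatially
    autocorrelated covariate fields calibrated to regional means and
    standard deviations, log-scale richness with simultaneous
    autoregressive error, degraded survey inventories), distance-band
    spatial weights with Moran's I permutation tests, Spearman-based
    within-hypothesis variable screening, bootstrap significance-frequency
    predictor selection, maximum-likelihood simultaneous autoregressive
    error (SAR) regression with lag-distance selection by AIC, split-line
    breakpoint regression, and stratified-subsampling robustness and
    inventory-completeness audits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
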