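Package: deltahab
Title: Delta-GAM Habitat Suitability Modelling for Trawl-Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-part (delta/hurdle) habitat suitability modelling for
    zero-inflated, overdispersed trawl-survey catch data. Provides synthetic
    seascape and stratified-random survey simulation, bathymetric terrain
    metrics (slope in degrees and rugosity in [0,1]), binomial-occurrence x
    negative-binomial-abundance generalized additive models combined by
    multiplication, all-subsets model selection by small-sample-corrected AIC
    (AICc) with Akaike weights, internal/external validation with Spearman
    correlation corrected for spatial autocorrelation (effective sample size,
    modified t-test) and ROC/AUC, and prediction mapping with ordinary-kriged,
    0-1 scaled model-error surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    mgcv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
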