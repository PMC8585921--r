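Package: trawlindex
Title: Abundance Indices and Effort-Reduction Diagnostics for Trawl Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring epipelagic forage communities from midwater
    trawl surveys when sampling effort is curtailed. Standardizes haul-level
    catch-per-unit-effort into annual relative-abundance indices with a
    delta-GLM (hurdle) model with AIC covariate selection and bootstrap or
    asymptotic-posterior uncertainty; quantifies the bias and precision cost of
    reduced effort via focal-year station-subset resampling, SE = SD/sqrt(n)
    extrapolation, and random-exclusion experiments; calibrates seabird
    chick-diet proportions against trawl indices to predict abundance in
    survey-poor years; and fits boosted-regression-tree species distribution
    models for krill with climatological anomaly mapping. A synthetic survey
    generator with known ground truth (stratified station grids, zero-inflated
    lognormal catches, linked diet series, smooth environmental response
    surfaces) makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
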