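Package: elmbloom
Title: Extreme Learning Machine Models for Algal Bloom Prediction in
    Regulated Rivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits extreme learning machine (ELM) regressors to weekly
    water-quality and weather time series to predict chlorophyll-a
    concentration, the standard proxy for algal-bloom intensity.  Provides
    the two feature designs used for weir pairs on regulated rivers (with
    and without the lagged upstream chlorophyll-a covariate), comparison
    baselines (multiple linear regression, a backpropagation neural
    network, and ANFIS with fuzzy c-means rule induction), model selection
    by hidden-node sweep, Nash-Sutcliffe/RMSE/AIC evaluation, and a
    calibrated synthetic generator of upstream/downstream weir-pair series
    for end-to-end testing without monitoring-network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
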