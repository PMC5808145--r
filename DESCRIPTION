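Package: richcast
Title: Hindcast Evaluation of Species Richness Forecasts with Observer
    Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for forecasting site-level species richness from
    survey panels with observer turnover, in the style of North American
    Breeding Bird Survey route analyses. Provides a synthetic panel
    generator with a calibrated site/observer/residual variance
    structure, a Gibbs-sampled hierarchical observer model whose
    posterior draws propagate observer uncertainty into downstream
    forecasts, six richness forecasters (site average, naive random
    walk, AICc-selected ARIMA, boosted regression trees, stacked
    per-species random forests, and a latent-factor joint species
    distribution model), bioclim-style environmental feature
    construction from monthly weather, and a forecast-verification
    suite (RMSE, prediction-interval coverage, Gaussian deviance,
    horizon curves, skill against baselines, and an exact
    site and annual squared-error decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
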