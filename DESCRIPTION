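Package: xisdew
Title: Daily Spatiotemporal Dew-Point Modeling by IDW-Baseline Residual Boosting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building daily spatiotemporal models of station-observed
    dew point with the XGBoost-IDW synthesis (XIS) approach: inverse-distance
    weighting supplies a baseline estimate at each station-day, and gradient
    boosted trees model the residual from gridded reanalysis aggregates,
    satellite column-water-vapor and static land-use predictors. Includes
    sub-daily observation cleaning and reduction to three daily dependent
    variables (T-min, mean, and T-max humidity), station-level cross-validation
    with weighted error metrics and regional breakdowns, baseline comparators,
    SHAP attribution summaries, hyperparameter search via maximin Latin
    hypercube designs, humidity thermodynamics (dew point from specific
    humidity, relative humidity, NWS heat index), and a synthetic-data
    generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xgboost,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
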