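Package: countyprev
Title: County-Level Small-Area Estimation of Obesity and Physical Activity Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-area estimation of county-level prevalence of obesity and
    leisure-time physical activity from individual survey microdata. Provides
    regression calibration of self-reported body mass index against
    examination-survey cell means, four hierarchical logistic model variants
    (naive, covariate, geospatial, full) with a two-stage neighbor-mean
    geospatial term fitted on moving five-year windows, race-poststratified
    and age-standardized prevalence estimates with simulation-based
    uncertainty intervals, model selection by down-sampling validation
    (Lin's concordance correlation, mean relative error, RMSE), an ecological
    regression of prevalence change, and a seeded synthetic-data generator
    that emulates the statistical structure the models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
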