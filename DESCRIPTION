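Package: heatmorb
Title: Estimation of Daily Heat-Illness Ambulance Transport Counts
Version: 0.1.0
Authors@R: person("heatmorb", "maintainers", email = "heatmorb@example.org", role = c("aut", "cre"))
Description: Tools for estimating the daily number of ambulance-transported
    heat-illness patients from summer weather. Includes a two-node (core/skin)
    human thermoregulation surrogate producing daily peak core-temperature
    increase and daily total sweating, exposure feature construction (short
    lag structures, heat-acclimatization weighted moving averages, WBGT), a
    nonlinear indoor/outdoor morbidity model with an age-dependent risk
    weighting, two-stage iterative least-squares fitting with leave-one-out
    cross-validation by year, an adaptation-window scan, evaluation metrics
    (R-squared, MAE per million population, F-tests, seasonal error profiles,
    hot-day stratification), and a seeded synthetic-data generator for
    multi-year weather, age pyramids and Poisson daily counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
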