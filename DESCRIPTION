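Package: scalesiacarbon
Title: Carbon Sequestration Modelling for Restored Scalesia pedunculata Stands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model the aboveground carbon sequestration potential of
    restored Scalesia pedunculata stands in Galapagos agroforestry systems.
    Includes a synthetic generator for quarterly plant-monitoring cohorts, a
    repeated-measures logistic mixed model of survival with plant and site
    random intercepts, a linear diameter-at-breast-height (DBH) estimator
    from plant age and height, two-compartment allometric dry-mass and
    carbon equations, a stochastic stand-level projection with multiplicative
    Brownian noise, and archipelago-scale carbon footprint offset accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    tools,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
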