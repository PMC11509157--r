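Package: bordertrap
Title: Spatial Analysis of Border Pheromone Trapping Effects on Orchard
    Fruit Damage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analyses how aggregation-pheromone traps deployed along an
    apple-orchard border reshape the spatial distribution of fruit damage
    by the brown marmorated stink bug (Halyomorpha halys). Implements
    six-class fruit damage scoring (incidence and severity), border
    polyline geometry and point-to-border distances, a distance-weighted
    trap catch index, log-link Poisson and negative binomial count
    regressions with offsets, backward AIC term selection, analysis of
    deviance, Pearson chi-square goodness of fit, distance-decay damage
    curves with the 50%-cumulated-damage distance, and the control-minus-
    trap differential effect with its crossover distance. A seeded
    synthetic orchard-trial generator reproduces the statistical structure
    of such trials so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    car,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
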