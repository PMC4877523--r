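Package: hybridveg
Title: Hybrid Continuous-Hydrology / Individual-Based Simulation of
    Dryland Vegetation Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates water-limited vegetation on a grid of soil parcels
    coupled to an explicit population of individual plants.  Surface and
    soil water follow continuous-time dynamics (rainfall, biomass-dependent
    infiltration, evaporation and drainage, plant uptake, lateral
    diffusion) integrated with a fourth-order Runge-Kutta scheme, while
    plants grow by a water-limited logistic metabolism and reproduce and
    die as discrete stochastic events (lognormal seed dispersal kernel,
    biomass-threshold stochastic mortality, age hazard).  The package
    reproduces the classical spot, labyrinth and gap self-organization of
    arid vegetation, and ships experiment presets for rainfall sweeps,
    dispersal-trait sweeps, sudden precipitation shifts and seasonal
    (sinusoidal) rainfall, together with quadrat-based spatial dispersion
    statistics (Lloyd's index of patchiness, David-Moore index of cluster
    size) and population-structure summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
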