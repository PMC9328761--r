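Package: actinload
Title: Load Adaptation of Branched Actin Networks: Ratchet Kinetics, Flux
    Balance, and Stochastic Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis and modelling of load adaptation in
    branched (dendritic) actin networks growing against a force clamp.
    Provides Brownian-Ratchet force laws for filament elongation and capping
    (including a bulky capping-protein variant and an internal tethering
    force), steady-state flux-balance analysis of AFM/TIRF measurements,
    an event-driven stochastic simulator of network growth under load,
    single-molecule incorporation-track analysis, a FRET-based estimator of
    WH2-domain occupancy, and seeded synthetic-data generators emulating the
    force-clamp and TIRF measurements so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
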