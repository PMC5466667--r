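Package: protocell
Title: Semi-Empirical Simulation of Metabolising, Dividing Lipid Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Couples minimal proto-metabolic reaction networks (a
    two-cycle 'heterotrophic' model PM1 and a three-cycle 'autotrophic'
    model PM2) to an osmotically regulated lipid vesicle whose solute
    permeability depends on membrane lipid composition. Provides a
    deterministic (adaptive Runge-Kutta) engine for steady-state and
    bistability analysis, an exact Gillespie engine for stochastic
    growth-and-division dynamics with lineage statistics, the
    dye-leakage assay pipeline that parameterises the composition to
    permeability map (exponential release fitting, permeability and
    diffusion coefficients, exact-matching polynomial calibration
    curves), and synthetic-data generators so every stage is testable
    without external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
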