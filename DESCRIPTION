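Package: lenscrowd
Title: Hard-Sphere Crowding Simulations and Assay Analytics for Lens
    Crystallin Transparency
Version: 0.1.0
Authors@R:
    person("Lens", "Crowding Project", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-driven molecular dynamics of polydisperse (optionally
    inelastic) hard spheres in a periodic box, with Lubachevsky-Stillinger
    compression, an Andersen thermostat, and species-resolved radial
    distribution functions and static structure factors, tailored to the
    crowding of alpha-, beta- and gamma-crystallin particles in the eye
    lens.  Also provides the statistical analytics used alongside such
    simulations: Boltzmann-sigmoid fits of PEG-turbidity solubility
    curves, turbidity-kinetics metrics, min-max fluorescence
    normalization, and surface-pressure (pendant-drop tensiometry)
    initial-rate and plateau statistics with ANOVA/Bonferroni testing and
    attractive/repulsive interaction calls.  Seeded synthetic-data
    generators emulate every assay so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
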