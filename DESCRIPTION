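Package: nanogswitch
Title: Bistable and Oscillatory Dynamics of the Nanog/Oct4-Sox2 Pluripotency Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a minimal transcription-factor
    network model of Nanog heterogeneity in mouse embryonic stem cells. The
    Oct4-Sox2 heterodimer maintains itself through positive auto-regulation and
    activates Nanog, which in addition auto-regulates via its dimer. Two
    mechanisms for the experimentally observed switching between Nanog-low and
    Nanog-high cells are implemented: noise-induced transitions in a bistable
    system, and noisy limit-cycle oscillations driven by a Nanog-activated
    transcriptional repressor X. The package provides deterministic fixed-point
    and one-parameter bifurcation analysis, Euler-Maruyama stochastic
    simulation of single cells and independent-cell ensembles, residence-time
    and population-distribution statistics, and drivers for in-silico
    experiments (cell sorting with re-establishment of the bimodal Nanog
    distribution, and gating of differentiation signals by the Nanog state).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
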