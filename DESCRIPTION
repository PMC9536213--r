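Package: tcsim
Title: Thalamocortical Circuit Construction and Simulation at Configurable Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and simulate somatosensory thalamocortical spiking
    circuits at desk scale. Provides probabilistic distance-dependent cortical
    wiring fitted from connectome instances (exponential, saturating-exponential
    and Gaussian profiles), a 29-class synapse registry with deterministic
    Tsodyks-Markram short-term plasticity and dual-exponential conductances,
    layered-cylinder and stacked-box cell placement, thalamic wiring by axonal
    footprint, divergence and convergence rules, reduced conductance-based point
    neurons with low-threshold calcium rebound bursting, a clock-driven network
    simulation engine with spike replay, calcium-dependent synaptic state
    switching, line-source local field potentials, and population analysis
    metrics (rates, ISI CV, synchrony, oscillation spectra).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
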