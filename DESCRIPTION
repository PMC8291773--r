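Package: poresim
Title: Multiscale Simulation of Protein Transport Through Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates protein translocation and resistive-pulse current signals in
    biological and synthetic nanopores by coupling a continuum electrokinetic model
    with Brownian dynamics. An axisymmetric finite-volume solver for the
    Poisson-Nernst-Planck-Stokes equations supplies position-dependent forces, ionic
    currents and electroosmotic flow; low-Reynolds-number hydrodynamics and plane-wall
    closed forms supply position- and direction-dependent diffusion tensors; a
    Brownian-dynamics integrator with hard-wall reflection evolves protein
    trajectories over precomputed force and current fields; a stochastic adsorption
    model (Poisson-distributed binding attempts, exponential durations with optional
    Bell-type force dependence) adds receptor and wall binding; and event analytics
    produce dwell-time distributions, blockade-amplitude scatter data and exponential
    dissociation-rate fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
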