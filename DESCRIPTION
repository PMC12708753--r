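Package: modfluct
Title: Moderately Interacting Particle Systems and Their Mean-Field
    Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and verification toolkit for moderately interacting
    stochastic particle systems with mollified attractive or repulsive Riesz
    (sub-Coulomb) interaction potentials on a periodic box. Provides the
    kernel construction (Riesz potential, convolution-square factor, bump
    mollifier family) as Fourier symbols and radial force tables, an
    Euler-Maruyama ensemble integrator for the interacting and intermediate
    particle systems with optional shared-noise coupling, pseudo-spectral
    solvers for the intermediate nonlocal aggregation-diffusion equation and
    the dual backward linearized flow, and the statistics that connect them:
    smoothed empirical-measure error norms and their decay rate in the
    particle number, law-of-large-numbers and coupling diagnostics, and a
    central-limit-theorem test of the fluctuation field against the variance
    predicted by the dual backward evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
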