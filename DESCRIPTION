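Package: pancfate
Title: Multicellular Modelling of Pancreatic Acinar-Islet Cell Fate Control
    by Lateral Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a multicellular gene-regulatory model of
    pancreatic exocrine/endocrine cell fate control in which a four-factor
    Hill-kinetics circuit per cell (Hnf6-, Ngn3-, Ptf1a- and Isl1-like
    factors) is coupled between adjacent cells by Delta-Notch-type lateral
    inhibition and by a lateral stabilization positive feedback. Provides
    hexagonal-lattice and minimal three-cell tissues, a seeded Heun-Maruyama
    stochastic integrator, Newton-based steady-state solving with analytic
    Jacobians, branch continuation and saddle-node (fold) detection, and
    canned in-silico protocols for development, acinar-to-islet
    transdifferentiation, recovery of stabilization, and cell-density or
    aggregate-shape sweeps of conversion efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
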