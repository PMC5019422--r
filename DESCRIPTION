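Package: dipdeR
Title: Population Density Simulation of Cortical Column Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulation of recurrently coupled homogeneous
    populations of leaky integrate-and-fire neurons by time evolution of
    the membrane-voltage probability density (a displacement
    integro-partial differential equation, DiPDE, solved with a
    conservative finite-volume scheme).  Ships a four-layer, two
    cell-type cortical column parameterization after Potjans and
    Diesmann (2014), stimulus protocols for step and sinusoidal laminar
    drive, linearity diagnostics (homogeneity, additivity, total
    harmonic distortion, amplitude-response cutoff), connectivity
    sensitivity ensembles, and a Monte-Carlo spiking-network oracle for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
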