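Package: cellreorient
Title: Stochastic Models of Cell Reorientation Under Cyclic Stretch
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the statistical distribution of orientation angles of
    cells cultured on a cyclically stretched elastic substratum. Implements
    an orthotropic elastic energy with its bifurcation analysis and
    closed-form equilibrium orientations, overdamped Langevin (SDE) and
    discrete-time kinetic jump processes for single-cell reorientation
    (including an optimal-control reorientation rule), the Fokker-Planck
    equations they induce on the periodic domain [0, pi) together with
    their Boltzmann-type stationary states, and the circular/first-quadrant
    statistics used to compare model output with published orientation
    histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
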