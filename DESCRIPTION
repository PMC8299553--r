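Package: langreg
Title: Langevin Regression for Nonlinear Stochastic System Identification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identification of nonlinear stochastic differential equations
    (Langevin models with drift and state-dependent diffusion) from a single
    long time series. Combines binned Kramers-Moyal conditional moment
    estimation, adjoint Fokker-Planck corrections for finite sampling
    intervals, Kullback-Leibler regularization against the empirical
    stationary density, and reverse-greedy stepwise sparse regression for
    structure discovery. Includes Euler-Maruyama simulators for benchmark
    systems (coloured-noise pitchfork, double-well potential, radial wake
    surrogate) and diagnostics such as dwell-time statistics, Welch power
    spectra and an Einstein-Markov subsampling scan.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
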