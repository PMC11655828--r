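Package: avol
Title: Attractor Network Model of Intentional Control with Nonlinear Dynamics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a multi-area delay differential attractor network of
    anterior cingulate and lateral prefrontal cortex (BA9, BA10, BA46, with a
    pre-SMA readiness-potential readout) with Freeman sigmoid gain, Hebbian
    plasticity and conduction delays, and orchestrates an iterative
    intentional-control protocol in which competing goal and action assemblies
    converge from chaotic to near-limit-cycle dynamics. Ships the matching
    nonlinear time-series battery: Takens delay embedding with automatic lag
    (average mutual information) and dimension (false nearest neighbours)
    selection, Grassberger-Procaccia correlation dimension, Rosenstein largest
    Lyapunov exponent, sample entropy, Hann spectrograms with band summaries,
    and theta-gamma phase-amplitude coupling with time-shift surrogates, plus
    benchmark signal generators (sine, Lorenz, Roessler, modulated gamma) for
    oracle testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    deSolve,
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
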