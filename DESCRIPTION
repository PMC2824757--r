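Package: stochsync
Title: Feedback-Amplified Stochastic Synchronization of Neural Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of self-organized stochastic
    synchronization in mitral-granule cell circuits of the olfactory bulb.
    Phase-oscillator and Morris-Lecar mitral cells receive shared and
    independent Poisson inhibitory kicks through their phase resetting
    curves; the shared rate is driven by a noisy leaky integrate-and-fire
    granule cell, closing a positive feedback loop between synchrony and
    input correlation. Includes the reduced event-driven map of the same
    system, the stationary phase-difference density computed from the
    discretized transfer operator, the averaged slow dynamics of the shared
    rate, and fixed-point and bistability analysis, together with
    reproducible figure-analogue experiment runners and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
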