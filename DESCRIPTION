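Package: earlyvision
Title: Early Visual Cortex Filter-Bank Models with a Trained Linear Readout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models of the earliest stages of primate visual processing
    (LGN-like difference-of-Gaussians filters and V1-like Gabor filter banks
    in simple-cell, complex-cell, and linear-receptive-field variants) feeding
    a trainable binary linear readout. Includes a synthetic face/non-face
    stimulus generator with matched low-level statistics, a composition stage
    that applies scale, rotation, and position-jitter nuisances over eight
    background types, repeated-split benchmark grids with percent-correct and
    d-prime summaries, and simulated-lesion analyses (spatial-frequency
    channel knockouts and weight-sign-consistency selections).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    png,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
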