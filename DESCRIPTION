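Package: ipdnet
Title: Spiking Neural Network Models of Interaural Phase Difference Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A laboratory for studying how small spiking neural networks learn to
    localize pure tones from binaural timing cues. Generates phase-delayed,
    Poisson-coded input spike trains parameterized by interaural phase difference
    (IPD), trains leaky integrate-and-fire classifiers with surrogate gradient
    descent (optionally under Dale's-law sign constraints and a firing-rate
    regularizer), learns input delays by two differentiable mechanisms (a
    translation-plus-interpolation delay layer and a single-nonzero-kernel
    temporal convolution), and analyzes trained networks via tuning-curve fits,
    a rate-based closed form, a six-parameter reduced model, and nonnegative
    tensor component analysis. Hot loops (spike generation, backpropagation
    through time, temporal convolution) are implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
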