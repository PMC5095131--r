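Package: aerorient
Title: Orientation-Invariant Object Recognition for Event Camera Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Recognizes objects moving in any of eight orientations from
    address-event representation (AER) streams, after training on samples
    moving in a single reference orientation. Implements bio-inspired
    S1/C1 feature extraction (a Gabor filter bank with event-driven
    convolution and a linear forgetting mechanism, followed by local MAX
    pooling), a dual Gaussian-blob tracker that estimates motion
    orientation from the centers of ON and OFF event clouds, an address
    lookup table that rotates feature addresses back to the reference
    frame, and a tempotron spiking-neuron classifier with time-to-first
    spike encoding and majority voting. Includes converters from
    grayscale images to event streams and a seeded generator of
    moving-glyph event streams for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
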