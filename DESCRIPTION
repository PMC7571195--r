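Package: spikecube
Title: Spiking Neural Network Reservoir Pipeline for Multimodal Emotion
    Valence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies binary emotional valence from multimodal
    physiological and facial-expression feature time series with a
    brain-inspired spiking neural network. Features are encoded into
    population spike trains by equal-count receptive fields, fed into a
    three-dimensional leaky integrate-and-fire reservoir with small-world
    connectivity trained by spike-timing-dependent plasticity, and read
    out by dynamic evolving spiking output neurons (rank-order
    initialisation plus drift) classified with K-nearest neighbours under
    leave-one-subject-out cross-validation. Includes extractors for ECG
    (FIR band-pass, Pan-Tompkins R detection), respiration, skin
    temperature, galvanic skin response, pupil diameter and facial
    landmark distances, a synthetic multimodal data generator for
    end-to-end testing, feature-level and decision-level fusion, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
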