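Package: eegentropy
Title: Entropy-Feature Fusion and Recurrent Classification for Cross-Subject
    EEG Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for recognising discrete emotional states
    (positive, neutral, negative) from multichannel EEG across subjects.
    Implements wavelet-based preprocessing of lateral-temporal channels
    (channel selection, anti-aliased downsampling to 256 Hz, 50 Hz notch,
    db6 decomposition into the five clinical bands, and threshold-based
    artifact suppression that halves wavelet coefficients exceeding the
    mean plus two standard deviations), five windowed entropy features
    (approximate, fuzzy, Renyi, differential, and five-scale multiscale
    sample entropy) over non-overlapping one-second windows, per-subject
    min-max feature normalisation and entropy-feature fusion, and
    sequence-to-sequence LSTM and bidirectional LSTM classifiers trained
    by backpropagation through time. A protocol-structured synthetic EEG
    generator with emotion-dependent band power and complexity, pink-noise
    background, and blink/movement artifacts makes the whole pipeline
    runnable and testable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
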