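Package: neurosign
Title: Multimodal Person Authentication from Dynamic Signatures and EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multimodal biometric identification and verification
    that combine online (dynamic) signatures with simultaneously recorded
    electroencephalography (EEG). Provides writing-direction features for
    pen trajectories, Hanning-windowed short-time DFT gamma-band features
    for multichannel EEG, a bidirectional long short-term memory (BLSTM)
    sequence classifier with softmax output, decision fusion by sum rule,
    Borda count and max rule, per-identity threshold calibration for
    genuine/forger verification, evaluation metrics (FAR, FRR, TPR, HTER,
    EER, DET curves), and a reproducible synthetic cohort generator that
    emulates a signing-while-recording acquisition protocol including
    skilled forgery attacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
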