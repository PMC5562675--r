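Package: seizr
Title: Subband-Energy PCA Features for Early Seizure Onset Detection in EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for early seizure onset detection from single-channel EEG
    using frequency-band energy features. Implements a difference-filtered
    short-time Fourier decomposition into the five conventional EEG subbands
    (delta, theta, alpha, beta, gamma), dominant-eigenvector features obtained
    by uncentered principal component analysis of pooled subband-energy
    vectors from training seizures (initial 5 s versus whole-seizure
    segments), threshold-based onset detection with false-positive,
    false-negative and latency metrology, per-seizure threshold calibration
    with median selection and scaled-threshold sweeps, stable-threshold-range
    ranking of competing features, a seeded generator of annotated synthetic
    ictal EEG (beta-dominant onsets, theta-dominant late phases, 1/f
    background, interictal spikes, line-noise bursts and movement artifacts),
    and EDF/CSV input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
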