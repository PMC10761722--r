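Package: ifstate
Title: Instantaneous-Frequency Microstate Analysis of Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments multichannel resting-state EEG into leading-phase
    microstates defined on the spatial distribution of Hilbert-transform
    instantaneous frequency (IF). Provides per-electrode IF estimation with
    phase-slip suppression, the spatial IF deviation field and its global
    field summary (GF-IF), k-means segmentation of the scalp field at GF-IF
    maxima with transitions at GF-IF minima, and microstate statistics
    (emergence frequency, occurrence-duration rate, transition
    probabilities). Includes a validation suite for GF-IF dynamics (Welch
    power spectra, multiscale sample entropy, IAAFT surrogates), group
    comparison and MMSE-correlation statistics with Benjamini-Hochberg FDR
    control, a seeded synthetic-cohort generator with ground truth, and
    readers for EDF and plain-matrix recordings.
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
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
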