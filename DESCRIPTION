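Package: phasesync
Title: Phase-Synchrony Connectivity Analysis for Multi-Trial Electrophysiology
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for inter-areal phase-synchrony analysis of
    multi-trial region-of-interest (ROI) time courses, as acquired in MEG/EEG
    source-space experiments. Provides a synthetic-data generator with known
    ground-truth oscillatory coupling, epoch-level preprocessing (baseline
    correction, amplitude-based trial rejection, trial-count equalization),
    continuous Morlet wavelet time-frequency decomposition, across-trial
    weighted phase lag index (WPLI) estimation with 10-ms window averaging,
    trial-shuffle surrogate inference, repeated-measures group statistics
    with Benjamini-Hochberg FDR correction, signal-detection d-prime, and
    directed lagged structural equation models (SEM) with bootstrap and
    permutation tests plus chi-square/RMSEA model comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
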