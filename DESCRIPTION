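Package: innerspeech
Title: Single-Unit Tuning and Population Decoding of Internal Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-unit electrophysiology recorded
    during a cued word-production task with internal (silent) and vocalized
    speech phases. Provides a validated on-disk session model (trial table,
    spike timestamps, task configuration), an inhomogeneous-Poisson
    synthetic-session generator with known ground truth, firing-rate
    estimation (50-ms binning, Gaussian smoothing, audio-onset alignment),
    word-tuning statistics (indicator regression against the inter-trial
    baseline and Kruskal-Wallis, with FDR control and session-level
    summaries), phase-wise word decoding (PCA features, shared-covariance
    LDA, leave-one-out cross-validation, shuffle-label significance,
    cross-phase generalization, simulated closed-loop online decoding), and
    demixed principal component analysis of the trial tensor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
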