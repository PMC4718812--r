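Package: odimaps
Title: Fourier Intrinsic-Signal Imaging Analysis of Ocular Dominance Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying experience-dependent plasticity in mouse
    primary visual cortex from periodic-stimulus intrinsic-signal optical
    imaging. Extracts per-pixel response amplitude and phase at the
    stimulation frequency by Fourier analysis, scores ocular dominance
    indices with smoothing, thresholding and run-block inclusion rules,
    measures retinotopic map quality as neighbourhood position scatter,
    analyses optomotor spatial-frequency and contrast-sensitivity
    thresholds, and runs the accompanying group-statistics battery
    (t-tests, Bonferroni-corrected ANOVA, repeated-measures ANOVA). A
    synthetic-data module renders ground-truth imaging movies and
    behavioral cohorts so the full pipeline is testable by parameter
    recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
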