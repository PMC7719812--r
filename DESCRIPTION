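Package: closurenet
Title: Perceptual Closure, Repetition Priming, and Directed Functional
    Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multimodal analysis of perceptual closure and
    repetition priming experiments. Generates fragmented-picture stimuli and
    ascending-method-of-limits presentation designs, simulates behavioral,
    EEG and BOLD data from known ground-truth models, extracts event-related
    potential component amplitudes (P1, N1, Ncl) with artifact rejection and
    repeated-measures statistics, fits first-level fMRI general linear models
    with canonical hemodynamic response regressors, and computes directed
    functional connectivity via vector autoregressive models and Geweke
    influence measures, including voxelwise difference Granger causality
    maps with bootstrap plus false-discovery-rate thresholding and
    nonparametric group inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
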