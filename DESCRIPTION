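Package: erpstates
Title: Oddball ERP Simulation, Topographic Statistics and Microstate Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates visual oddball EEG experiments with planted P1 and
    N1/N170 component topographies, preprocesses continuous recordings into
    artifact-corrected condition averages (zero-phase low-pass filtering,
    regression-based ocular correction, epoching, amplitude-threshold
    rejection, common-average re-referencing), measures component peaks and
    mean amplitudes with repeated-measures ANOVA (Greenhouse-Geisser
    correction, partial eta squared), computes reference-free topographic
    statistics (global field power, global map dissimilarity, point-wise
    randomization TANOVA), and segments event-related potentials into
    functional microstates by atomize-and-agglomerate hierarchical
    clustering with cross-validation model selection and per-subject
    back-fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    dplyr,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
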