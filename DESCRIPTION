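Package: phenomap
Title: Sleep, RBD-Like Event, Photometry and Brain-Map Phenotyping for Rodent Synucleinopathy Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the analysis chain used to phenotype
    a gut-seeded alpha-synuclein mouse model: rule-based EEG/EMG/activity sleep
    staging in 20-second epochs, detection of REM-sleep-without-atonia
    ("RBD-like") events from z-scored RMS-EMG, Welch periodogram band powers,
    sleep-aligned dual-channel fiber-photometry normalization, whole-brain
    ROI density mapping of DAB-stained sections with per-ROI group statistics,
    watershed-based aggregate cluster counting, a Bartlett-gated ANOVA
    decision tree with Dunnett comparisons and ROUT outlier exclusion, and
    deterministic behavioral indices. Ground-truth synthetic generators for
    every input make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    mvtnorm,
    signal,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    withr
Config/testthat/edition: 3
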