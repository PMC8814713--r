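Package: amss
Title: Adapted Murine Sepsis Score and Diagnostic Validation for
    Experimental Sepsis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores longitudinal monitoring records from experimental
    murine sepsis with the Adapted Murine Sepsis Score (A-MSS), a ten-item
    ordinal severity scale combining the seven observational Murine Sepsis
    Score items with binned rectal temperature, glycemia, and relative
    body-weight loss. Computes derived hematological severity indices
    (neutrophil-lymphocyte ratio, platelet-lymphocyte ratio, mean platelet
    volume to platelet-count ratio, baseline-relative platelet count) and
    the diagnostic-validation statistics used to evaluate the score: ROC
    curves with Youden-index cutoff selection, sensitivity and specificity,
    Pearson and Spearman correlation, and two-way factorial ANOVA
    (time by treatment) with Bonferroni post-tests. Includes a seeded
    simulator of two-arm longitudinal cohorts so the full scoring and
    validation pipeline can be exercised without animal data, and a
    command-line interface for scoring, diagnosis, simulation, and
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vctrs
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
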