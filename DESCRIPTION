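Package: cnacircuits
Title: Recurrent Copy-Number Alterations, Expression Subtypes, and
    Genomic Circuits in Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis pipeline for tumor cohorts profiled by
    segmented array-CGH, gene expression arrays, targeted mutation screens,
    and clinical follow-up. Calls per-probe copy-number states with
    sample-adaptive thresholds, detects focal amplifications and homozygous
    deletions, discovers recurrent regions (FGA/HD/MRD and arm-level events)
    by a peak-and-extend algorithm, computes genomic-complexity metrics
    (nFGA, fBAC, CIN expression score), clusters expression profiles into
    molecular subtypes, infers alteration co-occurrence networks by exact
    hypergeometric tests with Bonferroni control, and stratifies
    disease-specific survival. Ships a synthetic-cohort generator with
    planted ground truth so every stage is testable end to end.
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
    igraph,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
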