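Package: rmsurfaceome
Title: Surfaceome Target Prioritization for Rhabdomyosarcoma Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Target-prioritization pipeline for cell-surface proteomics of
    rhabdomyosarcoma cell lines and patient-derived xenografts. Starting from
    peptide-level label-free intensity tables, the package performs
    normalization, two-stage left-censored (MNAR) imputation, Top3 protein
    roll-up (iTop3), filtering against surface-protein annotation lists,
    multi-component proteomics and mRNA scoring with Top-K ranking, empirical
    Bayes moderated t-statistics and linear mixed-model group comparisons with
    Benjamini-Hochberg adjustment, and clinical validation utilities
    (immunohistochemistry H-scores, Kaplan-Meier curves with automatic
    best-cutoff dichotomization, logrank tests, univariate Cox regression).
    A synthetic-data module generates peptide tables, annotation lists, FPKM
    matrices and survival cohorts with planted ground truth so that every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    lme4,
    lmerTest,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
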