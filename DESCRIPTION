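Package: ewasmeta
Title: Meta-Analysis of Epigenome-Wide Association Studies of Childhood BMI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for consortium-style epigenome-wide
    association studies (EWAS) of child and adolescent body mass index.
    Provides LMS-based BMI standard-deviation scores and IOTF weight-status
    classification, per-CpG beta-value quality control (3*IQR outlier removal,
    probe exclusion and flagging), per-cohort Huber robust-regression and
    logistic EWAS, fixed-effects inverse-variance-weighted meta-analysis with
    Cochran's Q / I-squared heterogeneity, leave-one-out diagnostics,
    Bonferroni and Benjamini-Hochberg multiple-testing control, hypergeometric
    enrichment and effect-estimate correlation against previously published
    CpG sets, genomic-window annotation queries, and a synthetic multi-cohort
    data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
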