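Package: sepsismet
Title: Metabolome-Wide Screening and Diagnostic Modelling for Neonatal
    Sepsis versus Systemic Inflammation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted plasma metabolomics case-control studies in
    preterm neonates that distinguish late-onset sepsis from systemic
    inflammation without sepsis. Implements pooled-QC based feature filtering,
    Rosner (generalized ESD) sample outlier detection, derived-feature
    construction, quantile-regression imputation of left-censored data
    (QRILC), autoscaling, linear mixed-effects screening across five group
    contrasts with confounder adjustment and Benjamini-Hochberg control,
    trend-pattern classification, bootstrap-aggregated LASSO stability
    selection with leave-one-out cross-validated diagnostic panels, McNemar
    model comparison, and Spearman / differential correlation against routine
    inflammatory markers. Includes a synthetic-cohort generator with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    glmnet,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
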