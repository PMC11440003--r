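Package: raschdif
Title: Rasch Calibration, Fit Diagnostics, and Lasso-Penalised
    Differential Item Functioning for Dichotomous Checklists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Psychometric analysis pipeline for dichotomous screening
    checklists such as the 57-item Autism Behavior Checklist (ABC).
    Calibrates person abilities and item difficulties under the
    dichotomous Rasch model by joint maximum likelihood, computes
    WINSTEPS-style infit/outfit mean-square and standardized fit
    statistics with separation and reliability indices, assesses
    unidimensionality by principal component analysis of standardized
    residuals, and detects uniform differential item functioning (DIF)
    across person covariates with a lasso-penalised item response model
    selected by BIC along a regularisation path.  Includes a synthetic
    response generator with configurable demographic margins, trait
    impact, and planted DIF for validation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
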