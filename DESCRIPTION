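Package: metabosig
Title: Stratified Metabolite Signature Discovery and Classification
    Consistency for Case-Control Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers plasma phospholipid signatures that separate knee
    osteoarthritis patients from healthy volunteers in demographically
    stratified case-control cohorts, and compares classification models by
    their bootstrap train-test consistency.  Implements out-of-bag bootstrap
    AUC distributions for univariate metabolite pre-selection with a 2.5%
    quantile rule, one-component principal-component and partial-least-squares
    logistic classifiers alongside plain multivariate logistic regression,
    multivariate dispersion homogeneity testing with Tukey HSD, and a
    calibrated case-control cohort simulator (target univariate AUC, within
    lipid-class correlation, batch effects) for end-to-end testing when raw
    cohort data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
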