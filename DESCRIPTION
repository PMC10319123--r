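Package: rrnc
Title: Neural Congruency Analysis of Fixation-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Extracts correlated spatial components from fixation-locked
    EEG epochs recorded during serial rapid automatized naming (RAN)
    tasks. Components are obtained from a generalized eigenvalue
    decomposition of pooled between-subject and within-subject
    cross-covariance matrices; each participant is then scored for
    neural congruency with a reference group under leave-one-out
    component extraction. Congruency scores are aggregated into a
    cumulative metric and a LASSO-weighted metric (sparse logistic
    regression, leave-one-participant-out cross-validation), with
    group discrimination assessed by ROC AUC, permutation testing,
    and factorial ANOVA. A synthetic-cohort generator produces
    co-registered EEG and fixation streams with planted fixation-locked
    sources for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
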