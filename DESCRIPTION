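Package: ispip
Title: Integrated Structure-Based Protein Interface Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-classifier for protein-protein interface residue
    prediction. Integrates per-residue interface-likelihood scores from
    orthogonal structure-based predictors (template-based, template-free,
    docking-based) through linear, logistic, random-forest and
    gradient-boosted-tree models, with grouped five-fold cross-validation
    selected by average per-protein F-score. Includes ground-truth
    interface annotation from complex structures by a 4.0 Angstrom
    heavy-atom contact rule, rolling-probe solvent accessibility for
    surface-residue counting, docking-pose interface-frequency scoring,
    dynamic top-N threshold classification, confusion-matrix metrics
    (precision, recall, F, MCC), ROC and precision-recall curves with
    trapezoidal AUC, Kolmogorov-Smirnov model comparison, and a synthetic
    score/structure generator so the whole workflow runs end to end
    without external predictors.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    stats,
    utils,
    bio3d,
    rpart,
    xgboost,
    glmnet,
    nortest,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
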