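Package: epistack
Title: Stacked and Cascade Generalization for B-Cell Epitope Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Meta-learning toolkit for per-residue B-cell epitope prediction.
    Combines the per-residue scores of external epitope predictors with
    sequence-derived propensity features in stacked (two- and three-level) and
    cascade generalization hierarchies, using leakage-free out-of-fold meta
    features. Includes threshold grid search for base predictors, a full
    classifier-evaluation suite (confusion-matrix measures, MCC, F-score,
    ROC/AUC, stratified antigen-grouped cross-validation, paired t tests,
    reconstruction of confusion matrices from rounded published rates),
    Pearson/Spearman score-correlation and agreement-distribution analysis,
    greedy backward-elimination and forward-selection ablation of ensemble
    members, and a synthetic residue-level data generator with controlled
    epitope prevalence, per-predictor discrimination, and inter-predictor
    correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    pROC,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
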