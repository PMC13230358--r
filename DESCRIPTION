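Package: calibens
Title: Calibration-Aware Evaluation of Parallel Ensemble Decision Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining multi-class softmax predictions from parallel
    (bagging-style) ensembles of classifiers and for evaluating the resulting
    decisions with class-imbalance-aware detection metrics and calibration
    diagnostics. Implements majority voting, unweighted softmax averaging, and
    a rank-squared, balanced-accuracy-driven weighted averaging scheme for
    deriving base-model weights from cross-validation performance. The
    evaluation suite covers balanced accuracy, support-weighted one-vs-rest
    precision/recall/specificity/F1, one-vs-one ROC AUC, binned expected
    calibration error with reliability diagrams, bootstrap confidence
    intervals, pairwise z-test comparison tables, and aggregated ROC curves.
    A seeded synthetic-cohort generator emulates an imbalanced three-class
    neuroimaging study (cognitively normal, mild cognitive impairment,
    Alzheimer's disease) with controllable base-model accuracy and
    over/under-confidence, plus stratified train/test splitting by diagnosis,
    sex, and age bin.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
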