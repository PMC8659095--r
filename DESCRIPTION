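Package: screenaudit
Title: Evaluation and Bias Diagnosis for Structure-Based Virtual Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for evaluating scored virtual-screening benchmarks and
    diagnosing dataset bias. Aggregates per-pose, per-receptor docking scores
    into compound-level predictions (best pose, worst pose, pose-affinity
    product), computes early-recognition statistics (ROC-AUC, enrichment
    factor, normalized enrichment factor) with stratified bootstrap
    uncertainty, compares scoring methods with Mann-Whitney tests and paired
    per-target win counts, evaluates cross-docking pose ranking against an
    RMSD threshold, fits ligand-only simple-descriptor regression baselines to
    audit benchmarks for property bias, relates training-set fingerprint
    similarity to early enrichment, and generates synthetic benchmarks with
    known ground truth for end-to-end validation.
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
    glue,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    caret,
    e1071,
    glmnet,
    igraph,
    pROC,
    ranger,
    rpart,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
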