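Package: otubench
Title: Benchmarking and Interpreting Machine Learning Classifiers on
    Microbiome OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A rigorous benchmarking pipeline for microbiome-based binary
    classification. Reads mothur 'shared' OTU count tables, applies
    rarefaction and per-OTU min-max normalization, and evaluates seven
    classifier families (regularized logistic regression, L1/L2 linear
    support vector machines, RBF-kernel SVM, decision tree, random forest,
    gradient boosted trees) over many stratified 80/20 data splits with
    repeated stratified five-fold cross-validation for hyperparameter
    selection and held-out AUROC for evaluation. Models are interpreted by
    signed absolute-weight ranks (linear families) and by permutation
    importance with perfectly rank-correlated OTUs permuted jointly as
    groups; models are compared pairwise with a double-tailed empirical
    p-value over per-split AUROC differences. Includes a synthetic OTU-table
    generator with sparse heavy-tailed counts, correlated feature blocks and
    a controllable class signal so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    glmnet,
    e1071,
    rpart,
    ranger,
    xgboost,
    vegan,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
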