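Package: hepatens
Title: Hybrid Machine-Learning/Deep-Learning Ensembles for Hepatotoxicity QSAR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative structure-activity relationship (QSAR) pipeline for
    binary hepatotoxicity classification from SMILES. Curates compound tables
    (canonicalization, mixture/inorganic/ambiguous filters, deduplication),
    computes physicochemical descriptors, extended 2D topological descriptors
    and circular (Morgan-type/ECFP) fingerprints, ranks features and performs
    AUC-contribution sequential elimination, and fits heterogeneous ensembles
    (voting, bagging, stacking) over five-plus-one base learners including a
    small LSTM recurrent network and a multilayer perceptron. Evaluation covers
    confusion-matrix metrics, ROC/AUC, stratified k-fold cross-validation,
    repeated holdouts and one-way ANOVA comparisons, with seeded synthetic
    generators (planted-signal fingerprints and rule-labeled SMILES) for
    benchmarking every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    ranger,
    e1071,
    class,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
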