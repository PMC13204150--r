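Package: neuroboost
Title: Biomimetic Feature Selection and Hybrid Boosted Classifiers for
    EEG-Based Alzheimer's Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for two-class (healthy vs. Alzheimer's
    disease) classification of EEG-derived feature tables. Provides five
    train-then-transform feature extractors (PCA, kernel partial least
    squares, one-dimensional ordinary kriging, Isomap with out-of-sample
    embedding, and K-means centroid-distance features), seven biomimetic
    wrapper feature selectors (cuckoo search, rat swarm, their hybrid, zebra
    optimization, gravitational search, particle swarm, and the gravitational
    search-particle swarm hybrid) driven by a cross-validated k-nearest-
    neighbour fitness, and a zoo of hybrid boosted classifiers (extreme
    learning machine Adaboost, CART Adaboost, weighted broad learning system
    and its real-valued boosting ensemble, and a soft-voting committee).
    Includes a synthetic imbalanced two-class Gaussian-mixture generator,
    leakage-free repeated stratified k-fold cross-validation, and an
    extractor x selector x classifier experiment grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    igraph,
    e1071,
    randomForest,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
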