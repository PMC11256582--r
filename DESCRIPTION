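Package: sageDTI
Title: Drug-Target Interaction Prediction on an Implicit Drug-Target Pair
    Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts drug-target interactions by integrating heterogeneous
    drug and target association data into homogeneous similarity networks
    (Jaccard, Tanimoto and normalized Smith-Waterman similarities, threshold
    binarization and "see one, get one" OR-fusion), learning node embeddings
    with DeepWalk (truncated random walks plus skip-gram training), building
    an implicit drug-target pair network in which two pairs are adjacent when
    they share a drug or a target, refining pair features with a supervised
    GraphSAGE (fixed-fanout neighbor sampling with mean, pooling or LSTM
    aggregation), and classifying pairs with a random forest. Includes a
    seeded synthetic-data generator with planted cluster-matched interaction
    signal, stratified cross-validation, ranking of candidate pairs, network
    ablation modes, and a configuration-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    Biostrings,
    randomForest,
    e1071,
    rlang,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'sageDTI-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'metrics.R'
    'classify.R'
    'dtp.R'
    'graphsage.R'
    'crossval.R'
    'deepwalk.R'
    'io.R'
    'methods-accessors.R'
    'synthetic.R'
    'pipeline.R'
    'similarity.R'
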