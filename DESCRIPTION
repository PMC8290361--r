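Package: GenePairNet
Title: Disease-Gene Prioritization from GWAS and eQTL Summary Statistics
    with Graph-Convolutional Feature Smoothing and a CNN Pair Classifier
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate disease genes by integrating GWAS and
    eQTL summary p-values into per-gene feature blocks, smoothing the
    features over a weighted gene functional-interaction network with a
    graph-convolutional layer built on the self-looped symmetrically
    normalized adjacency operator, and scoring disease-gene pairs with a
    small convolutional neural network applied to a three-channel pair
    tensor (GWAS layer, eQTL layer, tiled disease-similarity row).
    Includes balanced negative sampling, stratified k-fold
    cross-validation with AUC/AUPR reporting, score-threshold screening
    of unknown pairs, and a synthetic summary-statistics generator with
    planted disease-gene signal for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: GenePrediction, NetworkInference, GraphAndNetwork,
    GenomeWideAssociation, Classification
RoxygenNote: 7.3.3
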