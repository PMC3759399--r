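Package: qsarvs
Title: Ligand-Based Virtual Screening with Consensus QSAR Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ligand-based virtual high-throughput screening toolkit for
    quantitative structure-activity relationship (QSAR) modelling on public
    bioassay data. Encodes small molecules as fixed-length descriptor vectors
    (scalar properties plus 2D/3D autocorrelation and radial distribution
    fingerprints of per-atom chemical properties), curates active/inactive
    sets from primary, confirmatory and counter screens by set algebra,
    builds stratified cross-validation plans with training, monitoring and
    independent partitions, trains artificial neural network, support vector
    regression, decision tree and Kohonen map models on pIC50-transformed
    activities, selects descriptor groups by information gain, F-score or
    sequential forward selection, and evaluates models with TNR-TPR curves,
    partial integrals, enrichment factors and consensus predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
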