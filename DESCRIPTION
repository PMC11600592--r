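Package: tsgcn
Title: Graph Attention Networks for Population Genetic Inference from Tree Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns population genetic quantities directly from sequences of
    marginal genealogical trees (tree sequences). Converts each marginal tree
    into a node-feature matrix and directed child-to-parent edge list, passes
    trees through a stack of attention-based graph convolution layers, and
    aggregates first across the nodes of each tree and then across the trees
    of each sequence with gated recurrent units, followed by a fully connected
    head. Ships featurization with training-set normalization, two tree
    downsampling schemes, hand-crafted per-tree and per-sequence summary
    statistics, a training loop with early stopping and task metrics (RMSE,
    R-squared, ROC AUC, average precision, confusion matrices), coalescent
    benchmark generators for recombination-rate regression, demographic
    parameter inference, introgression detection and sweep classification
    (driven by msprime through the system Python), ms-format ingestion, the
    alignment-CNN comparison path's seriation/assignment preprocessing and
    ResNet34-shape parameter accounting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with msprime and tskit on the PATH as
    'python' for the coalescent simulation backend; optionally Relate for
    genealogy inference from genotype matrices.
Config/testthat/edition: 3
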