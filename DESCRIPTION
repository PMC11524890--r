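Package: dualsyn
Title: Dual-View Graph Attention Modelling of Drug Combination Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts the synergy of a drug pair on a cancer cell line from two
    complementary views of the combination: a jointly constructed molecular
    graph of the two drugs processed by a multi-head graph attention network,
    and per-drug circular-fingerprint embeddings combined with a cell-line
    expression embedding. Includes replicate filtering of synergy screens,
    joint-graph construction strategies (super-edge, all-nodes, one and three
    super nodes), stratified leave-pair/cell/drug-out cross-validation,
    few-shot fine-tuning for unseen cell lines and drug pairs, a metric panel
    for regression and classification, and a self-contained synthetic fixture
    generator with a planted fingerprint-by-expression signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ChemmineR,
    ChemmineOB,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
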