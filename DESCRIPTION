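Package: ovanet
Title: Topology-Driven Analysis of RNAi Screens on Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw RNAi-screen phenotype measurements (egg laying and
    ovariole number counts with batch-matched controls) and a protein-protein
    interaction network into phenotype-specific gene sub-networks and novel
    gene predictions. Provides batch-standardised Z-score hit calling, seed
    list construction, hypergeometric and Monte-Carlo pathway enrichment,
    centrality-based hit prediction with ROC/AUC, degree-controlled network
    null models and modularity Z scores, a greedy Seed Connector Algorithm
    for module growth, meta-network grouping with label-permutation tests,
    and a synthetic-data generator with planted ground truth for validating
    every stage of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
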