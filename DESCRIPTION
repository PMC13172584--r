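Package: pugnn
Title: Positive-Unlabeled Graph Neural Networks for Disease Protein
    Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate disease-associated proteins on a
    protein-protein interaction network when only a small set of positive
    labels is available. Implements a frozen-feature graph convolutional
    scorer trained with four positive-unlabeled (PU) objectives (nnPU,
    Dist-PU, an edge-smoothness PU-GNN variant, and a belief-propagation
    GRAB variant), spy-based cross-validated evaluation, recall-weighted
    consensus ranking, random-walk and ablation baselines, hypergeometric
    enrichment-based candidate refinement, and per-node network topology
    profiling. Includes a seeded synthetic-data generator with planted
    disease modules so the whole pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    withr,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
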