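Package: pkamil
Title: Multi-Instance Graph Attention Networks for Aqueous pKa Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-atom (micro) acid dissociation constants and pools
    them into the most-acidic and most-basic macro-pKa of a molecule with a
    graph-attention message-passing network trained only on molecule-level
    labels (multi-instance learning). Includes structure standardization and
    ionizable-site enumeration from SMILES/SDF input, numerically stable
    micro-to-macro pooling, dataset splitting and regression metrics,
    dominant-site consistency analysis, Tanimoto similarity binning for
    applicability-domain assessment, Monte-Carlo-dropout uncertainty
    intervals, atomic-embedding similarity search, and a synthetic
    group-contribution data generator for end-to-end validation of the
    weakly supervised mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
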