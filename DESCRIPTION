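Package: hetesmir
Title: HeteSim-Based Prediction of Small Molecule-miRNA Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores potential associations between drug-like small molecules
    (SMs) and microRNAs by a meta-path constrained HeteSim relevance measure
    on a heterogeneous network built from known SM-miRNA associations, an
    integrated SM-SM similarity matrix, and an integrated miRNA-miRNA
    similarity matrix.  Provides readers and validators for association lists
    and labeled similarity matrices, weighted similarity integration, the
    six-path HeteSim scoring engine with decayed aggregation, global and
    local leave-one-out cross-validation, repeated k-fold cross-validation,
    a new-compound case-study protocol, and a block-structured synthetic
    network generator for fully offline testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
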