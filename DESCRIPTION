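Package: ppilbvs
Title: Ligand-Based Virtual Screening for Protein-Protein Interaction
    Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end ligand-based virtual screening (LBVS) workflow for
    discovering protein-protein interaction (PPI) inhibitors, modelled on a
    Keap1/Nrf2 screening campaign against a PPI-oriented compound library.
    Provides compound curation with activity thresholds and putative-inactive
    (decoy) negative sampling, functional-class circular fingerprints with
    Tanimoto similarity, dual random-forest activity classifiers trained with
    true-inactive and putative-inactive negative strategies, stratified
    cross-validation with the standard confusion-matrix and curve metrics,
    library ranking and availability-filtered candidate selection with a
    random comparator arm, TR-FRET assay simulation with a counter-assay
    specificity filter, and hit-rate estimation with extrapolation, novelty
    and substructure statistics. A synthetic compound universe generator
    emulates the statistical structure of the study inputs so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
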