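Package: synoclone
Title: Paired Blood/Synovial-Fluid Single-Cell Transcriptome and TCR
    Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for paired peripheral-blood (PB) and
    synovial-fluid (SF) single-cell RNA-seq plus single-cell TCR-seq
    data: quality-control filtering and multi-step doublet flagging,
    graph-based clustering with marker-rule annotation, clonotype
    calling and cluster-pair repertoire-overlap testing (one-sided
    Fisher's exact test with Benjamini-Hochberg FDR control),
    ligand-receptor interactome calling from a curated pair list, and
    closed-form immune-assay scores (Treg percent suppression,
    bead-standardized migration ratio, clinical disease activity
    index). Ships a synthetic paired-sample data generator with planted
    ground truth so every stage is testable without controlled-access
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
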