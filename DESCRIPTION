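Package: exoactivity
Title: Regulon-Based Transcription Factor Activity Analysis of Exocrine
    Pancreas and Pancreatic Tumor Single-Cell Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying transcription-factor regulatory activity in
    exocrine pancreas and pancreatic tumor cells from single-nucleus and
    single-cell RNA-seq count data. Provides adaptive quality-control
    filtering, bin-controlled marker-panel scoring with axis-based cell-state
    assignment, signed weighted regulon activity inference with technical
    covariate residualization, two-part hurdle association models with
    Stouffer/Fisher evidence combination and preranked GSEA export,
    gene-module and genotype-dose association models, tuned combined
    embeddings, minimum-spanning-tree pseudotime with redundancy-aware
    representative lineage selection, NMF-signature tumor family
    classification, and fully seeded synthetic data generators with planted
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    cluster,
    igraph,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, GeneRegulation, QualityControl,
    DifferentialExpression
RoxygenNote: 7.3.3
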