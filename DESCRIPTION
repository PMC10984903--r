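Package: myeloidStates
Title: Brain Myeloid Cell States Across Regional Pathology Gradients
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for single-nucleus RNA-seq of
    brain myeloid cells sampled across multiple brain regions and
    neuropathology severity groups. Provides nucleus-level quality control
    with per-sample MAD outlier filtering, marker-based myeloid subsetting,
    graph-based clustering with donor-specific cluster flagging,
    cluster-pathology association statistics (binomial enrichment, donor-level
    Spearman correlation with biochemical readouts, binary-covariate
    proportion tests), pathology-bin density-shift analysis, a two-part hurdle
    differential-expression test with donor and region covariates,
    principal-tree pseudotime with Moran's I trajectory-gene selection and
    transitional ("phasic") gene detection, pseudobulk negative-binomial
    region contrasts with control-group filtering, k-means gene-program
    clustering across regions with transition tracking and early-reversal
    detection, and public-signature comparison utilities. A synthetic-data
    generator emulating the study design (32 donors, 5 regions, 4 pathology
    groups, a regional tau gradient) makes every stage testable without the
    primary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, Clustering, DifferentialExpression,
    GeneExpression, Software
RoxygenNote: 7.3.3
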