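#' @import methods
#' @importFrom stats median mad sd var cor quantile rnorm rbinom rnbinom rbeta
#'   rmultinom runif setNames p.adjust pbinom pchisq pnorm pt phyper
#'   prop.test glm.fit binomial lm.fit aggregate complete.cases
#' @importFrom utils head combn
#' @importFrom Matrix colSums rowSums t sparseMatrix Diagonal crossprod
#'   readMM writeMM
NULL

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Synthetic study design configuration
#'
#' Describes the simulated cohort: donors nested in pathology groups, an
#' ordered brain-region panel sampled from each donor, the biochemical
#' readout model, the myeloid cluster composition, and nucleus-level QC
#' contamination rates. The defaults emulate a 32-donor cohort (8 donors in
#' each of 4 pathology severity groups) sampled in 5 regions ordered by
#' decreasing tau burden (EC > ITG > PFC > V2 > V1).
#'
#' @slot nDonors integer, number of donors.
#' @slot groups integer vector, pathology group (1..4) per donor.
#' @slot regions character, ordered region panel (most to least affected).
#' @slot nGenes integer, genes in the simulated matrix.
#' @slot nucleiPerSample integer, nuclei per donor x region sample.
#' @slot clusterSpec data.frame, one row per planted cluster: \code{name},
#'   \code{proportion}, \code{association} (none/positive/negative),
#'   \code{readout} (assay the association tracks), \code{beta} (tilt
#'   strength), \code{cellType} (microglia/PvM/monocyte), \code{latentCenter}
#'   (position on the homeostatic-to-disease axis).
#' @slot markerSpec data.frame, one row per marker gene: \code{gene},
#'   \code{cluster} (planted cluster name, or \code{"myeloid"} /
#'   \code{"nonmyeloid"} for compartment-wide markers), \code{logFC}.
#' @slot readoutSpec data.frame, one row per assay: \code{assay},
#'   \code{base}, \code{regionMult} (list column, 5 multipliers),
#'   \code{groupMult} (list column, 4 non-decreasing multipliers),
#'   \code{noiseSD} (lognormal sd).
#' @slot qcContamination numeric, fractions of high-mito / low-gene /
#'   low-UMI contaminant nuclei.
#' @slot nonmyeloidFraction numeric, fraction of non-myeloid nuclei.
#' @slot nPhasic,nMonotone integer, planted hump-shaped and monotone genes
#'   along the latent axis.
#' @slot phasicLogFC numeric, peak log-fold elevation of latent-axis genes.
#' @slot meanUMI numeric, expected library size of a clean nucleus.
#' @slot dispersion numeric, negative-binomial dispersion (1/size).
#' @slot seed integer, master seed.
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nDonors = "integer",
    groups = "integer",
    regions = "character",
    nGenes = "integer",
    nucleiPerSample = "integer",
    clusterSpec = "data.frame",
    markerSpec = "data.frame",
    readoutSpec = "data.frame",
    qcContamination = "numeric",
    nonmyeloidFraction = "numeric",
    nPhasic = "integer",
    nMonotone = "integer",
    phasicLogFC = "numeric",
    meanUMI = "numeric",
    dispersion = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@regions) != 5L)
        msg <- c(msg, "region list must have exactly 5 entries")
    if (anyDuplicated(object@regions))
        msg <- c(msg, "regions must be unique")
    if (length(object@groups) != object@nDonors)
        msg <- c(msg, "groups must have one entry per donor")
    if (length(object@groups) && !all(object@groups %in% 1:4))
        msg <- c(msg, "groups must be in 1..4")
    cs <- object@clusterSpec
    if (nrow(cs)) {
        if (abs(sum(cs$proportion) - 1) > 1e-8)
            msg <- c(msg, "cluster baseline proportions must sum to 1")
        if (!all(cs$association %in% c("none", "positive", "negative")))
            msg <- c(msg, "association must be none/positive/negative")
    }
    if (nrow(object@markerSpec) && any(object@markerSpec$logFC <= 0))
        msg <- c(msg, "marker log-fold elevations must be > 0")
    for (i in seq_len(nrow(object@readoutSpec))) {
        gm <- object@readoutSpec$groupMult[[i]]
        if (is.unsorted(gm))
            msg <- c(msg, "group multipliers must be non-decreasing in group")
        if (length(object@readoutSpec$regionMult[[i]]) != 5L)
            msg <- c(msg, "each assay needs 5 region multipliers")
    }
    qc <- object@qcContamination
    if (any(qc < 0) || any(qc > 1) || sum(qc) > 1)
        msg <- c(msg, "qc contamination fractions must lie in [0,1] and sum to <= 1")
    if (object@nonmyeloidFraction < 0 || object@nonmyeloidFraction > 1)
        msg <- c(msg, "nonmyeloidFraction must lie in [0,1]")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig Constructor with study-design defaults.
#'
#' @param nDonors Number of donors (default 32, 8 per group).
#' @param groups Integer pathology group per donor; defaults to 8 donors in
#'   each of groups 1..4.
#' @param regions Ordered region panel.
#' @param nGenes Number of genes.
#' @param nucleiPerSample Nuclei drawn per donor x region sample.
#' @param clusterSpec,markerSpec,readoutSpec Design tables; see slots.
#' @param qcContamination Named fractions \code{high_mito}, \code{low_gene},
#'   \code{low_umi}.
#' @param nonmyeloidFraction Fraction of non-myeloid nuclei.
#' @param nPhasic,nMonotone,phasicLogFC Latent-axis gene plan.
#' @param meanUMI,dispersion Count model parameters.
#' @param seed Master seed.
#' @return A validated \code{SimConfig}.
#' @export
SimConfig <- function(nDonors = 32L,
                      groups = rep(1:4, each = ceiling(nDonors / 4))[seq_len(nDonors)],
                      regions = c("EC", "ITG", "PFC", "V2", "V1"),
                      nGenes = 2000L,
                      nucleiPerSample = 60L,
                      clusterSpec = defaultClusterSpec(),
                      markerSpec = defaultMarkerSpec(),
                      readoutSpec = defaultReadoutSpec(),
                      qcContamination = c(high_mito = 0.03, low_gene = 0.03,
                                          low_umi = 0.02),
                      nonmyeloidFraction = 0.25,
                      nPhasic = 20L, nMonotone = 20L, phasicLogFC = 1.5,
                      meanUMI = 2500, dispersion = 0.5,
                      seed = 1L) {
    new("SimConfig",
        nDonors = as.integer(nDonors), groups = as.integer(groups),
        regions = as.character(regions), nGenes = as.integer(nGenes),
        nucleiPerSample = as.integer(nucleiPerSample),
        clusterSpec = clusterSpec, markerSpec = markerSpec,
        readoutSpec = readoutSpec,
        qcContamination = qcContamination,
        nonmyeloidFraction = nonmyeloidFraction,
        nPhasic = as.integer(nPhasic), nMonotone = as.integer(nMonotone),
        phasicLogFC = phasicLogFC, meanUMI = meanUMI,
        dispersion = dispersion, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nDonors, "donors x", length(object@regions),
        "regions,", object@nGenes, "genes,", object@nucleiPerSample,
        "nuclei/sample\n")
    cat("  clusters:", paste(object@clusterSpec$name, collapse = ", "), "\n")
    cat("  assays:  ", paste(object@readoutSpec$assay, collapse = ", "), "\n")
    cat("  seed:    ", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# QCThresholds / MarkerPanel / EmbeddingParams (lightweight parameter classes)
# ---------------------------------------------------------------------------

#' Nucleus-level QC thresholds
#'
#' The fixed filters applied to every nucleus (exonic read count, mito
#' fraction, detected genes, total UMIs) plus the per-sample MAD multiplier
#' used for the adaptive log-scale outlier filter.
#'
#' @slot minExonic,minGenes,minUMIs integer thresholds.
#' @slot maxMitoFraction numeric, maximum mitochondrial fraction.
#' @slot madMultiplier numeric, half-width of the per-sample log-MAD window.
#' @exportClass QCThresholds
setClass("QCThresholds", representation(
    minExonic = "integer", maxMitoFraction = "numeric",
    minGenes = "integer", minUMIs = "integer", madMultiplier = "numeric"))

setValidity("QCThresholds", function(object) {
    if (object@minExonic <= 0 || object@minGenes <= 0 || object@minUMIs <= 0 ||
        object@maxMitoFraction <= 0)
        return("all thresholds must be > 0")
    if (object@madMultiplier < 0) return("madMultiplier must be >= 0")
    TRUE
})

#' @describeIn QCThresholds Constructor; defaults are the study thresholds
#'   (exonic > 100, mito < 0.15, genes and UMIs >= 800, 3 MADs).
#' @param minExonic,maxMitoFraction,minGenes,minUMIs,madMultiplier thresholds.
#' @return A \code{QCThresholds} object.
#' @export
QCThresholds <- function(minExonic = 100L, maxMitoFraction = 0.15,
                         minGenes = 800L, minUMIs = 800L,
                         madMultiplier = 3.0) {
    new("QCThresholds", minExonic = as.integer(minExonic),
        maxMitoFraction = maxMitoFraction, minGenes = as.integer(minGenes),
        minUMIs = as.integer(minUMIs), madMultiplier = madMultiplier)
}

setMethod("show", "QCThresholds", function(object) {
    cat(sprintf(
        "QCThresholds: exonic > %d, mito < %.2f, genes >= %d, UMIs >= %d, %.1f MADs\n",
        object@minExonic, object@maxMitoFraction, object@minGenes,
        object@minUMIs, object@madMultiplier))
})

#' Myeloid marker panel
#'
#' @slot markers character, marker gene symbols.
#' @slot scoreThreshold numeric, per-nucleus mean-z cutoff for subsetting.
#' @exportClass MarkerPanel
setClass("MarkerPanel", representation(
    markers = "character", scoreThreshold = "numeric"))

setValidity("MarkerPanel", function(object) {
    if (!length(object@markers)) return("marker panel must be non-empty")
    if (anyDuplicated(object@markers)) return("marker symbols must be unique")
    TRUE
})

#' @describeIn MarkerPanel Constructor; defaults to the brain myeloid panel.
#' @param markers Marker symbols.
#' @param scoreThreshold Mean-z subsetting cutoff.
#' @return A \code{MarkerPanel}.
#' @export
MarkerPanel <- function(markers = c("P2RY12", "P2RY13", "ITGAM", "PTPRC",
                                    "CX3CR1", "SPI1", "C1QA", "C1QB",
                                    "TMEM119"),
                        scoreThreshold = 0) {
    new("MarkerPanel", markers = markers, scoreThreshold = scoreThreshold)
}

#' Embedding and clustering parameters
#'
#' @slot nPCs integer, principal components retained (default 30).
#' @slot nNeighbors integer, kNN size for the SNN graph.
#' @slot resolution numeric, Louvain resolution (0.2 for region-level work,
#'   0.4 for the cross-region object).
#' @slot nVarGenes integer, top-variable genes used for PCA.
#' @slot seed integer.
#' @exportClass EmbeddingParams
setClass("EmbeddingParams", representation(
    nPCs = "integer", nNeighbors = "integer", resolution = "numeric",
    nVarGenes = "integer", seed = "integer"))

setValidity("EmbeddingParams", function(object) {
    if (object@nPCs < 2) return("nPCs must be >= 2")
    if (object@resolution <= 0) return("resolution must be > 0")
    TRUE
})

#' @describeIn EmbeddingParams Constructor.
#' @param nPCs,nNeighbors,resolution,nVarGenes,seed see slots.
#' @return An \code{EmbeddingParams}.
#' @export
EmbeddingParams <- function(nPCs = 30L, nNeighbors = 20L, resolution = 0.2,
                            nVarGenes = 2000L, seed = 0L) {
    new("EmbeddingParams", nPCs = as.integer(nPCs),
        nNeighbors = as.integer(nNeighbors), resolution = resolution,
        nVarGenes = as.integer(nVarGenes), seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# ClusterResult
# ---------------------------------------------------------------------------

#' Graph-clustering result with embedding
#'
#' Per-nucleus cluster labels (0-based, ordered by decreasing cluster size)
#' together with the PCA embedding that produced them, per-cluster donor
#' composition, and the donor-specific flag (a cluster dominated > 75% by
#' one donor is excluded from biological interpretation).
#'
#' @slot labels integer, 0-based label per nucleus, named by barcode.
#' @slot pcs matrix, nuclei x PCs scores.
#' @slot rotation matrix, gene x PC loadings.
#' @slot geneMeans,geneSDs numeric, scaling parameters of the variable genes.
#' @slot varGenes character, genes used for the embedding.
#' @slot donorComposition matrix, cluster x donor nucleus counts.
#' @slot donorSpecific logical, per cluster.
#' @exportClass ClusterResult
setClass("ClusterResult", representation(
    labels = "integer", pcs = "matrix", rotation = "matrix",
    geneMeans = "numeric", geneSDs = "numeric", varGenes = "character",
    donorComposition = "matrix", donorSpecific = "logical"))

setValidity("ClusterResult", function(object) {
    msg <- character()
    labs <- sort(unique(object@labels))
    if (length(labs) && !identical(labs, 0:(length(labs) - 1L)))
        msg <- c(msg, "labels must be contiguous from 0")
    if (nrow(object@donorComposition)) {
        sizes <- tabulate(object@labels + 1L, nbins = nrow(object@donorComposition))
        if (!all(rowSums(object@donorComposition) == sizes))
            msg <- c(msg, "donor composition rows must sum to cluster sizes")
        if (length(object@donorSpecific) != nrow(object@donorComposition))
            msg <- c(msg, "donorSpecific must have one flag per cluster")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterResult", function(object) {
    k <- length(unique(object@labels))
    cat("ClusterResult:", length(object@labels), "nuclei in", k, "clusters\n")
    cat("  sizes:", paste(clusterSizes(object), collapse = ", "), "\n")
    if (any(object@donorSpecific))
        cat("  donor-specific:",
            paste(which(object@donorSpecific) - 1L, collapse = ", "), "\n")
})

#' @describeIn ClusterResult Per-nucleus labels (named integer, 0-based).
#' @param object A \code{ClusterResult}.
#' @export
clusterLabels <- function(object) object@labels

#' @describeIn ClusterResult Cluster sizes, in label order.
#' @export
clusterSizes <- function(object)
    tabulate(object@labels + 1L, nbins = length(object@donorSpecific))

#' @describeIn ClusterResult Donor-specific flags (logical per cluster).
#' @export
donorSpecific <- function(object) object@donorSpecific

#' @describeIn ClusterResult PCA scores (nuclei x PCs).
#' @export
embeddingPCs <- function(object) object@pcs

# ---------------------------------------------------------------------------
# TrajectoryResult
# ---------------------------------------------------------------------------

#' Principal-tree pseudotime result
#'
#' A minimum spanning tree over cluster centroids in PC space, rooted at the
#' homeostatic cluster; every nucleus is projected onto its nearest tree edge
#' and pseudotime is the geodesic distance from the root centroid to the
#' projection.
#'
#' @slot edges matrix, two columns of 0-based cluster ids (tree edges).
#' @slot centroids matrix, cluster x PC centroid coordinates.
#' @slot root,target integer, 0-based cluster ids.
#' @slot path integer, ordered cluster ids from root to target.
#' @slot pseudotime numeric, per nucleus, named by barcode.
#' @slot onPath logical, whether the nucleus projects onto the root-target
#'   path (the named trajectory).
#' @exportClass TrajectoryResult
setClass("TrajectoryResult", representation(
    edges = "matrix", centroids = "matrix", root = "integer",
    target = "integer", path = "integer", pseudotime = "numeric",
    onPath = "logical"))

setValidity("TrajectoryResult", function(object) {
    msg <- character()
    if (any(object@pseudotime < -1e-9)) msg <- c(msg, "pseudotime must be >= 0")
    if (length(object@path) &&
        (object@path[1] != object@root ||
         object@path[length(object@path)] != object@target))
        msg <- c(msg, "path must run from root to target")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TrajectoryResult", function(object) {
    cat("TrajectoryResult: root", object@root, "-> target", object@target,
        "| path:", paste(object@path, collapse = " -> "), "\n")
    cat(sprintf("  %d nuclei, %d on trajectory, pseudotime range [0, %.3f]\n",
                length(object@pseudotime), sum(object@onPath),
                max(object@pseudotime)))
})

#' @describeIn TrajectoryResult Per-nucleus pseudotime (named numeric).
#' @param object A \code{TrajectoryResult}.
#' @export
pseudotime <- function(object) object@pseudotime

#' @describeIn TrajectoryResult Logical, nuclei on the root-to-target path.
#' @export
onTrajectory <- function(object) object@onPath

# ---------------------------------------------------------------------------
# GeneClusterResult
# ---------------------------------------------------------------------------

#' Gene-program clustering result
#'
#' Genes summarised as z-scored regional expression profiles within one
#' pathology group and partitioned by seeded k-means; k is chosen by the
#' elbow rule over k = 1..10.
#'
#' @slot group character, pathology group the profiles come from.
#' @slot k integer, chosen number of clusters.
#' @slot labels integer, 1-based cluster label per gene, named by gene.
#' @slot centroids matrix, k x regions centroid z-profiles.
#' @slot profiles matrix, gene x region z-profiles.
#' @slot wss numeric, best within-cluster sum of squares for each k tried.
#' @exportClass GeneClusterResult
setClass("GeneClusterResult", representation(
    group = "character", k = "integer", labels = "integer",
    centroids = "matrix", profiles = "matrix", wss = "numeric"))

setValidity("GeneClusterResult", function(object) {
    msg <- character()
    if (length(object@labels) &&
        (min(object@labels) < 1L || max(object@labels) > object@k))
        msg <- c(msg, "labels must lie in 1..k")
    if (nrow(object@profiles)) {
        m <- rowMeans(object@profiles)
        s <- apply(object@profiles, 1, sd)
        if (max(abs(m)) > 1e-8 || max(abs(s - 1)) > 1e-6)
            msg <- c(msg, "profiles must be z-scored per gene")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "GeneClusterResult", function(object) {
    cat(sprintf("GeneClusterResult (group %s): %d genes, k = %d\n",
                object@group, length(object@labels), object@k))
    cat("  sizes:", paste(tabulate(object@labels, object@k), collapse = ", "),
        "\n")
})

#' @describeIn GeneClusterResult Per-gene cluster labels (1-based).
#' @param object A \code{GeneClusterResult}.
#' @export
geneClusters <- function(object) object@labels

#' @describeIn GeneClusterResult Gene x region z-profiles.
#' @export
geneProfiles <- function(object) object@profiles
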