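# End-to-end orchestration of the analysis stages on a simulated cohort.

#' Run the full analysis pipeline on a simulated cohort
#'
#' Chains the stages end to end: simulate readouts and counts, QC-filter,
#' subset myeloid nuclei by marker score, cluster (SNN-Louvain), flag
#' donor-specific clusters, run the pathology associations (binomial
#' enrichment and donor-level readout correlation in the most affected
#' region), bin the tau readout and compute density shifts, build the
#' homeostatic-to-disease pseudotime with trajectory-gene selection and
#' phasic detection, and run the pseudobulk region contrast
#' (group 4 vs group 1 control filter) plus gene-program clustering with
#' transitions. All stages derive their randomness from \code{cfg@seed}
#' and the fixed stage seeds, so a rerun with the same config is
#' byte-identical.
#'
#' @param cfg A [SimConfig].
#' @param qcThresholds A [QCThresholds] scaled to the config (the default
#'   is sized for the full-depth study data; pass smaller gene/UMI floors
#'   for small simulations).
#' @param params An [EmbeddingParams] for the clustering stage.
#' @param outDir Optional directory: per-stage CSV outputs are written
#'   there (deterministically formatted).
#' @return Named list with the per-stage objects: \code{readouts},
#'   \code{sce}, \code{qc}, \code{myeloid} (kept barcodes),
#'   \code{clusters}, \code{enrichment}, \code{correlation}, \code{bins},
#'   \code{density}, \code{trajectory}, \code{trajectoryGenes},
#'   \code{phasic}, \code{contrast} (control-filtered group-4 DE),
#'   \code{programs} (per-group [GeneClusterResult-class]),
#'   \code{transitions}.
#' @export
runPipeline <- function(cfg = SimConfig(),
                        qcThresholds = QCThresholds(),
                        params = EmbeddingParams(resolution = 0.4),
                        outDir = NULL) {
    readouts <- simulateReadouts(cfg)
    sce <- simulateCounts(cfg, readouts)
    qc <- suppressWarnings(qcFilter(sce, qcThresholds))
    sce2 <- sce[, qc$kept]
    norm <- normalizeLog(SummarizedExperiment::assay(sce2, "counts"))
    scores <- myeloidScore(norm)
    myeloid <- subsetMyeloid(scores, regions = setNames(sce2$region,
                                                        colnames(sce2)))
    sce3 <- sce2[, myeloid]
    norm3 <- norm[, myeloid]
    donors <- setNames(sce3$donor, colnames(sce3))
    clusters <- clusterGraph(norm3, params, donors = donors)
    clusters <- flagDonorSpecific(clusters)

    groups <- setNames(as.character(sce3$group), colnames(sce3))
    enrichment <- suppressWarnings(binomialEnrichment(clusters, groups))
    regionTop <- cfg@regions[1]
    meta <- data.frame(donor = sce3$donor, row.names = colnames(sce3))
    roTop <- readouts[readouts$region == regionTop, ]
    correlation <- proportionCorrelation(clusters, meta, roTop)

    bins <- binReadouts(readouts, "ptau_ratio")
    density <- densityShift(clusters, bins,
                            setNames(sce3$sample, colnames(sce3)))

    # orient the trajectory by the disease-associated signature
    damSig <- meanSignatureExpression(
        norm3, clusters, c("APOE", "SPP1", "CD9", "ITGAX", "TREM2"))
    micro <- annotateCellTypes(clusters, norm3) == "microglia"
    sigM <- damSig[names(micro)[micro]]
    rootLab <- as.integer(names(which.min(sigM)))
    targetLab <- as.integer(names(which.max(sigM)))
    trajectory <- NULL; trajGenes <- NULL; phasic <- NULL
    if (rootLab != targetLab) {
        trajectory <- buildPseudotime(clusters, rootLab, targetLab)
        if (sum(onTrajectory(trajectory)) >= 100) {
            trajGenes <- selectTrajectoryGenes(trajectory, norm3, clusters)
            sel <- trajGenes$gene[trajGenes$selected]
            if (length(sel))
                phasic <- phasicGenes(trajectory, norm3, sel)
        }
    }

    pb <- pseudobulk(SummarizedExperiment::assay(sce3, "counts"),
                     SummarizedExperiment::colData(sce3))
    rA <- cfg@regions[1]; rB <- cfg@regions[5]
    de4 <- regionContrast(pb, 4L, rA, rB)
    de1 <- regionContrast(pb, 1L, rA, rB)
    contrast <- controlFilter(de4, de1)
    programs <- list(
        g1 = kmeansProfiles(pb, 1L, seed = params@seed),
        g4 = kmeansProfiles(pb, 4L, seed = params@seed))
    transitions <- clusterTransitions(programs$g1, programs$g4)

    out <- list(readouts = readouts, sce = sce, qc = qc, myeloid = myeloid,
                clusters = clusters, enrichment = enrichment,
                correlation = correlation, bins = bins, density = density,
                trajectory = trajectory, trajectoryGenes = trajGenes,
                phasic = phasic, contrast = contrast, programs = programs,
                transitions = transitions)
    if (!is.null(outDir)) writePipeline(out, outDir)
    out
}

# deterministic text serialisation of the headline pipeline outputs
writePipeline <- function(res, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) utils::write.csv(
        format(as.data.frame(x), digits = 12),
        file.path(dir, f), row.names = FALSE)
    wr(res$qc$report, "qc_report.csv")
    wr(data.frame(barcode = names(clusterLabels(res$clusters)),
                  label = clusterLabels(res$clusters)), "clusters.csv")
    wr(res$enrichment, "enrichment.csv")
    wr(res$correlation, "correlation.csv")
    wr(res$density$density, "density.csv")
    if (!is.null(res$trajectory))
        wr(data.frame(barcode = names(pseudotime(res$trajectory)),
                      pseudotime = pseudotime(res$trajectory),
                      onPath = onTrajectory(res$trajectory)),
           "pseudotime.csv")
    if (!is.null(res$phasic)) wr(res$phasic, "phasic.csv")
    wr(res$contrast, "contrast.csv")
    wr(data.frame(gene = names(geneClusters(res$programs$g4)),
                  cluster = geneClusters(res$programs$g4)),
       "programs_g4.csv")
    writeLines(as.character(res$transitions$json),
               file.path(dir, "transitions.json"))
    invisible(dir)
}
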