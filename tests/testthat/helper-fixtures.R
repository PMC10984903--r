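# Shared fixture builders. Everything is generated in code; sizes are kept
# small so each file runs in seconds.

# compact study config: full 32-donor grid but few nuclei/genes
smallConfig <- function(seed = 1L, nucleiPerSample = 15L, nGenes = 300L,
                        ...) {
    SimConfig(nucleiPerSample = nucleiPerSample, nGenes = nGenes,
              seed = seed, ...)
}

# microglia-only config for trajectory work: no PvM/Mono/non-myeloid, no
# contamination, so almost every nucleus sits on the latent axis
trajectoryConfig <- function(seed = 1L, nucleiPerSample = 4L,
                             nGenes = 120L, phasicLogFC = 1.5) {
    cs <- data.frame(
        name = c("HOM", "TRANS", "DAM"),
        proportion = c(0.4, 0.2, 0.4),
        association = "none", readout = NA_character_, beta = 0,
        cellType = "microglia",
        latentCenter = c(0.08, 0.5, 0.92))
    ms <- data.frame(gene = c("P2RY12", "TMEM119"), cluster = "myeloid",
                     logFC = 2.0)
    # more ramp than hump genes so the latent axis dominates the cluster
    # geometry and the centroid MST chains HOM - TRANS - DAM
    SimConfig(nucleiPerSample = nucleiPerSample, nGenes = nGenes,
              clusterSpec = cs, markerSpec = ms,
              qcContamination = c(high_mito = 0, low_gene = 0, low_umi = 0),
              nonmyeloidFraction = 0, nPhasic = 10L, nMonotone = 20L,
              phasicLogFC = phasicLogFC, seed = seed)
}

simPair <- function(cfg) {
    ro <- simulateReadouts(cfg)
    list(readouts = ro, sce = simulateCounts(cfg, ro))
}

# deterministic two-blob expression fixture: genes x (2n) matrix with two
# well-separated populations
twoBlobMatrix <- function(n = 60L, nGenes = 50L, shift = 4, seed = 7L) {
    set.seed(seed)
    base <- matrix(rpois(nGenes * 2 * n, 5), nGenes, 2 * n)
    base[1:10, seq_len(n)] <- base[1:10, seq_len(n)] + rpois(10 * n, shift * 5)
    rownames(base) <- sprintf("G%03d", seq_len(nGenes))
    colnames(base) <- sprintf("C%03d", seq_len(2 * n))
    base
}

# ClusterResult straight from truth labels of a simulated object
truthClusters <- function(sce, norm = NULL) {
    if (is.null(norm))
        norm <- normalizeLog(SummarizedExperiment::assay(sce, "counts"))
    clusterResultFromLabels(
        setNames(sce$true_cluster, colnames(sce)), norm,
        donors = setNames(sce$donor, colnames(sce)),
        params = EmbeddingParams(nPCs = 20L))
}

# brute-force Moran's I double sum (independent of the package formula)
moranBrute <- function(x, W) {
    n <- length(x)
    xc <- x - mean(x)
    num <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
        num <- num + W[i, j] * xc[i] * xc[j]
    (n / sum(W)) * num / sum(xc^2)
}

# independent brute-force re-application of the five rules, nucleus by
# nucleus (no vectorised shortcuts shared with the implementation)
bruteQC <- function(report, thr) {
    kept <- logical(nrow(report))
    for (i in seq_len(nrow(report))) {
        r <- report[i, ]
        kept[i] <- r$exonic_counts > thr@minExonic &&
            r$mito_fraction < thr@maxMitoFraction &&
            r$detected_genes >= thr@minGenes &&
            r$total_umis >= thr@minUMIs
    }
    for (smp in unique(report$sample)) {
        idx <- which(report$sample == smp & kept)
        if (length(idx) < 3) next
        for (col in c("detected_genes", "total_umis")) {
            v <- log(report[[col]][idx])
            med <- median(v)
            madv <- median(abs(v - med))
            for (k in seq_along(idx))
                if (abs(v[k] - med) > thr@madMultiplier * madv)
                    kept[idx[k]] <- FALSE
        }
    }
    kept
}

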