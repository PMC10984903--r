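# Synthetic cohort generator: emulates a 32-donor, 5-region, 4-group
# snRNA-seq study of brain myeloid cells with a regional tau gradient,
# planted cell states, latent-axis (homeostatic -> disease) genes, and
# QC-failing contaminant nuclei. All randomness flows from SimConfig@seed.

#' Default planted cluster composition
#'
#' Six myeloid states: homeostatic microglia (HOM, depleted with tau),
#' transitioning microglia (TRANS, mid latent axis), disease-associated
#' microglia (DAM, enriched with tau), a ribosome-response state (RIBO),
#' perivascular macrophages (PvM) and monocytes (Mono). Baseline
#' proportions sum to 1; association tilts the per-sample mixing weight by
#' \code{exp(beta * z(readout))} before renormalisation.
#'
#' @return data.frame usable as \code{clusterSpec} in [SimConfig()].
#' @export
defaultClusterSpec <- function() {
    data.frame(
        name = c("HOM", "TRANS", "DAM", "RIBO", "PvM", "Mono"),
        proportion = c(0.40, 0.10, 0.25, 0.05, 0.12, 0.08),
        association = c("negative", "none", "positive", "none", "none", "none"),
        readout = c("ptau_ratio", NA, "ptau_ratio", NA, NA, NA),
        beta = c(0.8, 0, 1.0, 0, 0, 0),
        cellType = c("microglia", "microglia", "microglia", "microglia",
                     "PvM", "monocyte"),
        latentCenter = c(0.10, 0.50, 0.90, NA, NA, NA),
        stringsAsFactors = FALSE)
}

#' Default marker-gene plan
#'
#' Compartment-wide myeloid markers (the subsetting panel), the PvM panel
#' (LYVE1/MRC1/CD163/F13A1), the monocyte marker CCR2, per-state markers,
#' and non-myeloid (neuronal/oligodendrocyte) markers for the planted
#' non-myeloid contaminating fraction.
#'
#' @return data.frame usable as \code{markerSpec} in [SimConfig()].
#' @export
defaultMarkerSpec <- function() {
    rbind(
        data.frame(gene = c("P2RY12", "P2RY13", "ITGAM", "PTPRC", "CX3CR1",
                            "SPI1", "C1QA", "C1QB", "TMEM119"),
                   cluster = "myeloid", logFC = 2.5),
        data.frame(gene = c("LYVE1", "MRC1", "CD163", "F13A1"),
                   cluster = "PvM", logFC = 2.5),
        data.frame(gene = c("CCR2", "VCAN"), cluster = "Mono", logFC = 2.5),
        data.frame(gene = c("APOE", "SPP1", "CD9", "ITGAX", "TREM2"),
                   cluster = "DAM", logFC = 1.0),
        data.frame(gene = c("RPS6X", "RPL13X"), cluster = "RIBO", logFC = 1.0),
        data.frame(gene = c("SNAP25", "PLP1", "GFAP", "RBFOX3"),
                   cluster = "nonmyeloid", logFC = 2.5))
}

#' Default biochemical readout model
#'
#' Four assays per donor x region sample: pTau/Total tau ratio, HT7
#' aggregated tau, HEK seeding activity (IFD), and 3D6 amyloid-beta area
#' fraction. Tau assays decay along EC > ITG > PFC > V2 > V1; the amyloid
#' assay peaks in neocortex (ITG/PFC). Group multipliers are non-decreasing
#' with pathology group; noise is multiplicative lognormal with unit mean.
#'
#' @return data.frame usable as \code{readoutSpec} in [SimConfig()].
#' @export
defaultReadoutSpec <- function() {
    data.frame(
        assay = c("ptau_ratio", "ht7_tau", "hek_seeding", "ab_3d6"),
        base = c(0.05, 100, 50, 0.5),
        regionMult = I(list(c(1.0, 0.8, 0.6, 0.4, 0.3),
                            c(1.0, 0.7, 0.5, 0.35, 0.25),
                            c(1.0, 0.75, 0.55, 0.4, 0.3),
                            c(0.8, 1.0, 1.0, 0.7, 0.6))),
        groupMult = I(list(c(1, 2, 4, 8),
                           c(1, 2, 5, 10),
                           c(1, 1.5, 4, 9),
                           c(1, 3, 6, 8))),
        noiseSD = c(0.3, 0.4, 0.4, 0.4),
        stringsAsFactors = FALSE)
}

#' Simulate per-sample biochemical pathology readouts
#'
#' One row per donor x region. The expected value of each assay is
#' \code{base * regionMult[region] * groupMult[group]}; observed values are
#' that expectation times a unit-mean lognormal noise factor
#' \code{exp(rnorm(1, -sd^2/2, sd))}, so with \code{noiseSD = 0} the draw
#' equals the expectation exactly.
#'
#' @param cfg A [SimConfig].
#' @return data.frame with columns \code{donor}, \code{region},
#'   \code{group}, one column per assay, and matching \code{<assay>_expected}
#'   columns.
#' @export
simulateReadouts <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    set.seed(cfg@seed)
    donors <- sprintf("D%02d", seq_len(cfg@nDonors))
    grid <- expand.grid(region = cfg@regions, donor = donors,
                        stringsAsFactors = FALSE)[, c("donor", "region")]
    grid$group <- cfg@groups[match(grid$donor, donors)]
    ridx <- match(grid$region, cfg@regions)
    for (i in seq_len(nrow(cfg@readoutSpec))) {
        rs <- cfg@readoutSpec[i, ]
        mu <- rs$base * rs$regionMult[[1]][ridx] * rs$groupMult[[1]][grid$group]
        sdv <- rs$noiseSD
        noise <- if (sdv > 0) exp(rnorm(nrow(grid), -sdv^2 / 2, sdv)) else 1
        grid[[rs$assay]] <- mu * noise
        grid[[paste0(rs$assay, "_expected")]] <- mu
    }
    grid$sample <- paste(grid$donor, grid$region, sep = "_")
    grid
}

# Latent-axis expression multipliers. Hump genes peak mid-axis; monotone
# genes ramp up with a logistic. t in [0,1]; NA (non-microglial) -> 1.
.bumpMult <- function(t, lfc) {
    m <- exp(lfc * exp(-(t - 0.5)^2 / (2 * 0.12^2)))
    m[is.na(t)] <- 1
    m
}
.rampMult <- function(t, lfc) {
    m <- exp(lfc * stats::plogis((t - 0.5) / 0.12))
    m[is.na(t)] <- 1
    m
}

#' Simulate the gene x nucleus count matrix and nucleus metadata
#'
#' Negative-binomial counts per nucleus with lognormal library-size factors.
#' Each sample's cluster mixing weights start at the configured baselines
#' and, for clusters with a readout association, are tilted by
#' \code{exp(+/- beta * z(readout))} and renormalised, so cluster
#' proportions track the planted pathology gradient. Marker genes are
#' elevated by their configured log-fold change in their cluster; hump and
#' ramp genes vary along a latent homeostatic-to-disease axis carried by
#' microglial nuclei. Contaminant nuclei (high mito fraction, shrunken
#' libraries) are injected at the configured rates, and a non-myeloid
#' fraction carries neuronal/glial instead of myeloid markers.
#'
#' @param cfg A [SimConfig].
#' @param readouts Output of [simulateReadouts()] covering the same grid.
#' @return A [SingleCellExperiment::SingleCellExperiment] with sparse
#'   \code{counts}, per-nucleus metadata and per-nucleus truth
#'   (\code{true_cluster}, \code{latent_t}, \code{contaminant},
#'   \code{is_myeloid}) in \code{colData}, per-gene truth (\code{role}) in
#'   \code{rowData}, and the config + readouts in \code{metadata}.
#' @export
simulateCounts <- function(cfg, readouts) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    cs <- cfg@clusterSpec
    ms <- cfg@markerSpec
    if (cfg@nGenes < nrow(ms) + cfg@nPhasic + cfg@nMonotone)
        stop("nGenes smaller than the total marker + latent-axis gene list")
    donors <- sprintf("D%02d", seq_len(cfg@nDonors))
    samples <- paste(rep(donors, each = length(cfg@regions)),
                     cfg@regions, sep = "_")
    if (!all(samples %in% readouts$sample))
        stop("readouts do not cover the configured donor x region grid")
    set.seed(cfg@seed + 1L)

    # gene universe: markers, then latent-axis genes, then filler
    phasicGenes <- sprintf("HUMP%03d", seq_len(cfg@nPhasic))
    monoGenes <- sprintf("RAMP%03d", seq_len(cfg@nMonotone))
    filler <- sprintf("GENE%04d",
                      seq_len(cfg@nGenes - nrow(ms) - cfg@nPhasic - cfg@nMonotone))
    genes <- c(ms$gene, phasicGenes, monoGenes, filler)
    role <- c(paste0("marker:", ms$cluster),
              rep("phasic", cfg@nPhasic), rep("monotone", cfg@nMonotone),
              rep("none", length(filler)))
    baseWeight <- exp(rnorm(cfg@nGenes, 0, 1.2))
    # the subsetting panel genes are well-expressed in real myeloid nuclei
    # (P2RY12-class genes sit in the upper expression tier)
    baseWeight[which(ms$cluster == "myeloid")] <-
        baseWeight[which(ms$cluster == "myeloid")] * 5
    baseWeight <- baseWeight / sum(baseWeight)

    # per-sample mixing weights tilted by the associated readout
    zscore <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
    ro <- readouts[match(samples, readouts$sample), , drop = FALSE]
    mix <- matrix(rep(cs$proportion, each = length(samples)),
                  nrow = length(samples),
                  dimnames = list(samples, cs$name))
    for (j in seq_len(nrow(cs))) {
        if (cs$association[j] == "none") next
        z <- zscore(ro[[cs$readout[j]]])
        sgn <- if (cs$association[j] == "positive") 1 else -1
        mix[, j] <- mix[, j] * exp(sgn * cs$beta[j] * z)
    }
    mix <- mix / rowSums(mix)
    stopifnot(all(abs(rowSums(mix) - 1) < 1e-12))

    qc <- cfg@qcContamination
    sexes <- setNames(rep(c("M", "F"), length.out = cfg@nDonors), donors)
    tdp43 <- setNames(seq_len(cfg@nDonors) %in%
                      seq(2, cfg@nDonors, length.out = min(7, cfg@nDonors)),
                      donors)
    n <- cfg@nucleiPerSample
    blocks <- vector("list", length(samples))
    metas <- vector("list", length(samples))
    size <- if (cfg@dispersion > 0) 1 / cfg@dispersion else Inf

    for (s in seq_along(samples)) {
        smp <- samples[s]
        donor <- ro$donor[s]
        isNonMyeloid <- runif(n) < cfg@nonmyeloidFraction
        cl <- character(n)
        cl[isNonMyeloid] <- "NonMyeloid"
        nMy <- sum(!isNonMyeloid)
        if (nMy > 0)
            cl[!isNonMyeloid] <- sample(cs$name, nMy, replace = TRUE,
                                        prob = mix[s, ])
        ct <- ifelse(cl == "NonMyeloid", "other",
                     cs$cellType[match(cl, cs$name)])
        lat <- rep(NA_real_, n)
        mg <- ct == "microglia"
        if (any(mg)) {
            ctr <- cs$latentCenter[match(cl[mg], cs$name)]
            ctr[is.na(ctr)] <- 0.5
            lat[mg] <- pmin(1, pmax(0, rnorm(sum(mg), ctr, 0.10)))
        }
        contaminant <- rep("none", n)
        u <- runif(n)
        contaminant[u < qc[["high_mito"]]] <- "high_mito"
        contaminant[u >= qc[["high_mito"]] &
                    u < qc[["high_mito"]] + qc[["low_gene"]]] <- "low_gene"
        contaminant[u >= qc[["high_mito"]] + qc[["low_gene"]] &
                    u < sum(qc)] <- "low_umi"

        libFactor <- exp(rnorm(n, 0, 0.3))
        libFactor[contaminant == "low_gene"] <- libFactor[contaminant == "low_gene"] * 0.10
        libFactor[contaminant == "low_umi"] <- libFactor[contaminant == "low_umi"] * 0.22
        targetLib <- cfg@meanUMI * libFactor

        # per-nucleus mean vector: base weights x cluster/marker/axis effects
        mu <- matrix(baseWeight, nrow = cfg@nGenes, ncol = n)
        for (m in seq_len(nrow(ms))) {
            hit <- switch(ms$cluster[m],
                          myeloid = ct %in% c("microglia", "PvM", "monocyte"),
                          nonmyeloid = ct == "other",
                          cl == ms$cluster[m])
            if (any(hit)) mu[m, hit] <- mu[m, hit] * exp(ms$logFC[m])
            # myeloid panel genes are nearly silent outside the compartment
            if (ms$cluster[m] == "myeloid" && any(!hit))
                mu[m, !hit] <- mu[m, !hit] * exp(-1.5)
        }
        iPh <- nrow(ms) + seq_len(cfg@nPhasic)
        iMo <- nrow(ms) + cfg@nPhasic + seq_len(cfg@nMonotone)
        mu[iPh, ] <- mu[iPh, ] * rep(.bumpMult(lat, cfg@phasicLogFC), each = cfg@nPhasic)
        mu[iMo, ] <- mu[iMo, ] * rep(.rampMult(lat, cfg@phasicLogFC), each = cfg@nMonotone)
        mu <- sweep(mu, 2, targetLib / colSums(mu), `*`)

        cnt <- matrix(
            if (is.finite(size)) rnbinom(length(mu), mu = as.vector(mu), size = size)
            else stats::rpois(length(mu), as.vector(mu)),
            nrow = cfg@nGenes)
        blocks[[s]] <- methods::as(methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                                               "generalMatrix"), "CsparseMatrix")

        # clean nuclei: Beta on [0, 0.15) so they pass the mito rule by
        # construction; contaminants shifted above 0.15
        mito <- 0.15 * rbeta(n, 2, 10)
        hm <- contaminant == "high_mito"
        mito[hm] <- 0.15 + 0.85 * rbeta(sum(hm), 2, 5)
        umis <- colSums(cnt)
        metas[[s]] <- data.frame(
            barcode = sprintf("%s_N%04d", smp, seq_len(n)),
            donor = donor, region = ro$region[s], group = ro$group[s],
            sex = sexes[[donor]], sample = smp,
            tdp43_positive = tdp43[[donor]],
            exonic_counts = as.integer(round(umis * runif(n, 1.2, 2.0))),
            mito_fraction = mito,
            total_umis = as.integer(umis),
            detected_genes = colSums(cnt > 0),
            true_cluster = cl, cell_type = ct, latent_t = lat,
            contaminant = contaminant,
            is_myeloid = ct != "other",
            stringsAsFactors = FALSE)
    }

    counts <- do.call(cbind, blocks)
    meta <- do.call(rbind, metas)
    rownames(counts) <- genes
    colnames(counts) <- meta$barcode
    rownames(meta) <- meta$barcode
    stopifnot(all(Matrix::colSums(counts) == meta$total_umis))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(meta),
        rowData = S4Vectors::DataFrame(gene = genes, role = role,
                                       row.names = genes),
        metadata = list(config = cfg, readouts = readouts))
    sce
}

#' Write a simulated dataset to plain-text files
#'
#' Emits \code{matrix.mtx} (Matrix Market, genes x nuclei),
#' \code{features.tsv}, \code{barcodes.tsv}, \code{nucleus_meta.csv},
#' \code{readouts.csv} and \code{truth.csv} under \code{dir}.
#'
#' @param sce Output of [simulateCounts()].
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sce, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(SummarizedExperiment::assay(sce, "counts"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(sce), file.path(dir, "features.tsv"))
    writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
    cd <- as.data.frame(SummarizedExperiment::colData(sce))
    truthCols <- c("barcode", "true_cluster", "cell_type", "latent_t",
                   "contaminant", "is_myeloid")
    utils::write.csv(cd[, setdiff(colnames(cd), setdiff(truthCols, "barcode"))],
                     file.path(dir, "nucleus_meta.csv"), row.names = FALSE)
    utils::write.csv(cd[, truthCols], file.path(dir, "truth.csv"),
                     row.names = FALSE)
    ro <- S4Vectors::metadata(sce)$readouts
    if (!is.null(ro))
        utils::write.csv(ro, file.path(dir, "readouts.csv"), row.names = FALSE)
    invisible(dir)
}

#' Read a dataset written by [writeSimulation()] (or any MTX triplet)
#'
#' @param dir Directory holding \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv} and optionally \code{nucleus_meta.csv}.
#' @return A \code{SingleCellExperiment}.
#' @export
readCountsMTX <- function(dir) {
    m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
    rownames(m) <- readLines(file.path(dir, "features.tsv"))
    colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
    cd <- NULL
    metaFile <- file.path(dir, "nucleus_meta.csv")
    if (file.exists(metaFile)) {
        cd <- utils::read.csv(metaFile, stringsAsFactors = FALSE)
        rownames(cd) <- cd$barcode
        cd <- S4Vectors::DataFrame(cd[colnames(m), , drop = FALSE])
    }
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        colData = if (is.null(cd)) S4Vectors::DataFrame(row.names = colnames(m)) else cd)
}
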