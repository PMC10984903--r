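# Pseudobulk aggregation, NB region contrasts, control filtering, gene
# programs, transitions, readout correlation, early-reversal genes.

# direct pseudobulk-level NB simulator: genes x (2 regions x nPer samples)
# within one group, with optional planted region fold changes
simPB <- function(nGenes = 80L, nPer = 8L, dispersion = 0.3, seed = 1L,
                  lfc = NULL, group = 4L) {
    set.seed(seed)
    mu0 <- exp(rnorm(nGenes, 4, 1))
    lib <- exp(rnorm(2 * nPer, 0, 0.2))
    fc <- rep(1, nGenes)
    if (!is.null(lfc)) fc[seq_along(lfc)] <- 2^lfc
    counts <- matrix(0L, nGenes, 2 * nPer,
                     dimnames = list(sprintf("G%03d", seq_len(nGenes)),
                                     sprintf("S%02d", seq_len(2 * nPer))))
    for (j in seq_len(2 * nPer)) {
        mu <- mu0 * lib[j] * (if (j <= nPer) fc else 1)
        counts[, j] <- rnbinom(nGenes, mu = mu, size = 1 / dispersion)
    }
    cd <- S4Vectors::DataFrame(
        sample = colnames(counts),
        donor = sprintf("D%02d", seq_len(2 * nPer)),
        region = rep(c("EC", "V1"), each = nPer),
        group = group,
        sex = rep(c("M", "F"), nPer),
        row.names = colnames(counts))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
}

test_that("pseudobulk equals exact per-sample sums", {
    cfg <- smallConfig(seed = 91L, nucleiPerSample = 6L, nGenes = 100L)
    sce <- simPair(cfg)$sce
    counts <- SummarizedExperiment::assay(sce, "counts")
    meta <- as.data.frame(SummarizedExperiment::colData(sce))
    pb <- pseudobulk(counts, meta)
    pbm <- SummarizedExperiment::assay(pb, "counts")
    # brute-force per-gene loop oracle on a few samples
    for (smp in colnames(pbm)[c(1, 50, 160)]) {
        bc <- rownames(meta)[meta$sample == smp]
        for (g in c(1, 50, 100))
            expect_identical(pbm[g, smp],
                             as.integer(sum(counts[g, bc])))
    }
    # one nucleus per sample -> pseudobulk equals the nucleus column
    one <- counts[, 1:3]
    m1 <- data.frame(sample = paste0("s", 1:3), donor = "d", region = "EC",
                     group = 1, row.names = colnames(one))
    pb1 <- pseudobulk(one, m1)
    expect_equal(unname(as.matrix(SummarizedExperiment::assay(pb1))),
                 unname(as.matrix(one)))
    # split-and-remerge additivity
    meta2 <- meta
    relab <- meta2$sample
    half <- seq_len(nrow(meta2)) %% 2 == 0
    meta2$sample <- paste0(relab, ifelse(half, "_a", "_b"))
    pb2 <- pseudobulk(counts, meta2)
    merged <- SummarizedExperiment::assay(pb2)[, paste0(colnames(pbm), "_a")] +
        SummarizedExperiment::assay(pb2)[, paste0(colnames(pbm), "_b")]
    expect_equal(unname(merged), unname(pbm))
})

test_that("identical region profiles give null contrasts", {
    pb <- simPB(nGenes = 50L, seed = 3L)
    # copy region A's samples into region B -> identical columns
    y <- SummarizedExperiment::assay(pb)
    y[, 9:16] <- y[, 1:8]
    SummarizedExperiment::assay(pb) <- y
    de <- regionContrast(pb, 4L, "EC", "V1")
    expect_true(all(abs(de$log2FC) < 1e-6, na.rm = TRUE))
    expect_false(any(de$deg, na.rm = TRUE))
})

test_that("NB Wald reduces to an independent Poisson GLM as dispersion vanishes", {
    pb <- simPB(nGenes = 20L, dispersion = 1e-4, seed = 7L)
    de <- regionContrast(pb, 4L, "EC", "V1", dispersion = 0)
    y <- SummarizedExperiment::assay(pb)
    cd <- SummarizedExperiment::colData(pb)
    lib <- colSums(y)
    off <- log(lib * myeloidStates:::.tmmFactors(y))
    reg <- as.numeric(cd$region == "EC")
    sex <- as.numeric(cd$sex == "F")
    for (g in c(1, 5, 12)) {
        fit <- glm(y[g, ] ~ reg + sex + offset(off), family = poisson())
        sm <- summary(fit)$coefficients
        expect_equal(de$log2FC[g], sm["reg", "Estimate"] / log(2),
                     tolerance = 1e-6)
        expect_equal(de$p[g], sm["reg", "Pr(>|z|)"], tolerance = 1e-6)
    }
})

test_that("planted four-fold genes pass the DEG filters across seeds", {
    hits <- 0L; nSeed <- 10L
    for (s in seq_len(nSeed)) {
        pb <- simPB(nGenes = 60L, dispersion = 0.3, seed = 600 + s,
                    lfc = rep(2, 5))
        de <- regionContrast(pb, 4L, "EC", "V1")
        if (all(de$deg[1:5])) hits <- hits + 1L
    }
    expect_gte(hits, nSeed - 1L)
})

test_that("confounded or undersized designs are refused", {
    pb <- simPB(nGenes = 20L, seed = 9L)
    cd <- SummarizedExperiment::colData(pb)
    cd$sex <- ifelse(cd$region == "EC", "M", "F")
    SummarizedExperiment::colData(pb) <- cd
    expect_error(regionContrast(pb, 4L, "EC", "V1"), "confounded")
    pb2 <- simPB(nGenes = 20L, nPer = 2L, seed = 9L)
    expect_error(regionContrast(pb2, 4L, "EC", "V1"), "samples per region")
})

test_that("control filtering drops constitutive genes and keeps disease-only ones", {
    deG4 <- data.frame(gene = c("A", "B", "C", "D"),
                       log2FC = c(2, 2, 0.1, 1.5),
                       p = c(1e-5, 1e-6, 0.5, 1e-4))
    deG1 <- data.frame(gene = c("A", "B", "C"),
                       p = c(0.001, 0.8, 0.9))
    out <- suppressWarnings(controlFilter(deG4, deG1))
    expect_identical(attr(out, "dropped"), "A")
    expect_setequal(out$gene, c("B", "C", "D"))
    expect_true(is.na(out$pControl[out$gene == "D"]))
})

test_that("k-means selects the planted number of archetype programs", {
    set.seed(12)
    arch <- rbind(c(2, 1, 0, -1, -2), c(-2, -1, 0, 1, 2), c(-1, 2, -1, 2, -1))
    nPer <- 60L
    prof <- arch[rep(1:3, each = nPer), ] + matrix(rnorm(3 * nPer * 5, 0, 0.2),
                                                   3 * nPer)
    counts <- round(exp(prof + 5))
    storage.mode(counts) <- "integer"
    rownames(counts) <- sprintf("G%03d", seq_len(nrow(counts)))
    colnames(counts) <- c("EC", "ITG", "PFC", "V2", "V1")
    cd <- S4Vectors::DataFrame(sample = colnames(counts), donor = "D",
                               region = colnames(counts), group = 4L,
                               sex = "M", row.names = colnames(counts))
    pb <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    res <- kmeansProfiles(pb, 4L, seed = 2L)
    expect_identical(res@k, 3L)
    truth <- rep(1:3, each = nPer)
    # ARI via mclust-free contingency computation
    tab <- table(geneClusters(res), truth)
    a <- sum(choose(tab, 2)); b <- sum(choose(rowSums(tab), 2))
    cc <- sum(choose(colSums(tab), 2)); n <- sum(tab)
    ari <- (a - b * cc / choose(n, 2)) /
        ((b + cc) / 2 - b * cc / choose(n, 2))
    expect_gte(ari, 0.95)
    # k = 1 WSS equals the total scatter of the z-profiles
    Z <- geneProfiles(res)
    Zc <- sweep(Z, 2, colMeans(Z))
    expect_equal(unname(res@wss["1"]), sum(Zc^2), tolerance = 1e-8)
    # seeded determinism
    res2 <- kmeansProfiles(pb, 4L, seed = 2L)
    expect_identical(geneClusters(res2), geneClusters(res))
    # cross-check the k-means objective against stats::kmeans at k = 3
    km <- stats::kmeans(geneProfiles(res), centers = 3, nstart = 50,
                        iter.max = 15)
    expect_lt(abs(res@wss["3"] - km$tot.withinss) /
              max(km$tot.withinss, 1), 0.02)
})

test_that("transitions conserve genes and track a planted block swap", {
    set.seed(19)
    labsA <- setNames(rep(1:3, each = 40), sprintf("G%03d", 1:120))
    profiles <- matrix(rnorm(120 * 5), 120, 5,
                       dimnames = list(names(labsA), NULL))
    profiles <- t(scale(t(profiles)))
    mk <- function(labs, grp) new("GeneClusterResult", group = grp,
                                  k = 3L, labels = labs,
                                  centroids = matrix(0, 3, 5),
                                  profiles = profiles,
                                  wss = c(`3` = 1))
    resA <- mk(labsA, "1")
    # identical clustering: diagonal transition, rows 100%
    tr <- clusterTransitions(resA, mk(labsA, "2"))
    expect_true(all(tr$counts[upper.tri(tr$counts)] == 0) &&
                all(tr$counts[lower.tri(tr$counts)] == 0))
    expect_true(all(diag(tr$percent) == 100))
    expect_identical(unname(rowSums(tr$counts)),
                     as.numeric(table(labsA)))
    # swap one archetype block: exactly that block moves
    labsB <- labsA
    labsB[41:80] <- 1L
    labsB[1:40] <- 2L
    tr2 <- clusterTransitions(resA, mk(labsB, "2"))
    expect_identical(unname(tr2$counts["1", ]), c(0L, 40L, 0L))
    expect_identical(unname(tr2$counts["2", ]), c(40L, 0L, 0L))
    expect_identical(unname(tr2$counts["3", ]), c(0L, 0L, 40L))
    expect_error(clusterTransitions(resA, mk(setNames(rep(1L, 5),
        sprintf("X%d", 1:5)), "2")), "disjoint")
})

test_that("cluster scores track readouts and reversal genes are flagged", {
    # profile exactly proportional to the readout -> rho = 1
    counts <- matrix(10L, 20, 5,
                     dimnames = list(sprintf("G%03d", 1:20),
                                     c("EC", "ITG", "PFC", "V2", "V1")))
    grad <- c(32L, 16L, 8L, 4L, 2L)
    counts[1:10, ] <- matrix(rep(grad * 20L, each = 10), 10)
    counts[11:20, ] <- matrix(rep(rev(grad) * 20L, each = 10), 10)
    cd <- S4Vectors::DataFrame(sample = colnames(counts), donor = "D",
                               region = colnames(counts), group = 4L,
                               sex = "M", row.names = colnames(counts))
    pb <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    res <- kmeansProfiles(pb, 4L, k = 2L, seed = 1L)
    ro <- data.frame(sample = colnames(counts),
                     ptau_ratio = as.numeric(grad))
    pc <- profileReadoutCorrelation(res, pb, ro, assays = "ptau_ratio")
    expect_equal(max(pc$rho), 1, tolerance = 1e-12)
    expect_equal(min(pc$rho), -1, tolerance = 1e-12)  # anti-gradient cluster
    # early reversal: exact negation is flagged, identity is not
    z1 <- t(scale(t(matrix(c(-1.26, -0.63, 0, 0.63, 1.26,
                             -1.26, -0.63, 0, 0.63, 1.26), 2, 5,
                           byrow = TRUE,
                           dimnames = list(c("gRev", "gStable"), NULL)))))
    z2 <- z1
    z2["gRev", ] <- -z1["gRev", ]
    mk <- function(z, grp) new("GeneClusterResult", group = grp, k = 1L,
                               labels = setNames(rep(1L, 2), rownames(z)),
                               centroids = matrix(0, 1, 5), profiles = z,
                               wss = c(`1` = 1))
    rev <- earlyReversalGenes(mk(z1, "1"), mk(z2, "2"))
    expect_equal(rev$correlation[rev$gene == "gRev"], -1)
    expect_true(rev$flagged[rev$gene == "gRev"])
    expect_equal(rev$correlation[rev$gene == "gStable"], 1)
    expect_false(rev$flagged[rev$gene == "gStable"])
    expect_identical(rev$gene[1], "gRev")   # sorted most-reversed first
})

test_that("planted reversal genes are separated from stable genes under noise", {
    set.seed(29)
    nRev <- 40L; nStable <- 160L
    base <- matrix(rnorm((nRev + nStable) * 5), nRev + nStable, 5)
    base <- t(scale(t(base)))
    rownames(base) <- sprintf("G%03d", seq_len(nRev + nStable))
    noisy <- function(z) t(scale(t(z + matrix(rnorm(length(z), 0, 0.4),
                                              nrow(z)))))
    z1 <- noisy(base)
    z2 <- base
    z2[seq_len(nRev), ] <- -z2[seq_len(nRev), ]
    z2 <- noisy(z2)
    mk <- function(z, grp) new("GeneClusterResult", group = grp, k = 1L,
                               labels = setNames(rep(1L, nrow(z)),
                                                 rownames(z)),
                               centroids = matrix(0, 1, 5), profiles = z,
                               wss = c(`1` = 1))
    rev <- earlyReversalGenes(mk(z1, "1"), mk(z2, "2"))
    sens <- mean(rev$flagged[match(sprintf("G%03d", seq_len(nRev)),
                                   rev$gene)])
    fpr <- mean(rev$flagged[match(sprintf("G%03d", nRev + seq_len(nStable)),
                                  rev$gene)])
    expect_gte(sens, 0.9)
    expect_lte(fpr, 0.05)
})

test_that("NB Wald type-I error is calibrated under a 2000-gene null", {
    set.seed(99)
    nGenes <- 2000L
    mu0 <- exp(rnorm(nGenes, 4, 1)); lib <- exp(rnorm(16, 0, 0.2))
    counts <- sapply(seq_len(16), function(j)
        rnbinom(nGenes, mu = mu0 * lib[j], size = 1 / 0.3))
    rownames(counts) <- sprintf("G%04d", seq_len(nGenes))
    colnames(counts) <- sprintf("S%02d", 1:16)
    cd <- S4Vectors::DataFrame(sample = colnames(counts),
                               donor = colnames(counts),
                               region = rep(c("EC", "V1"), each = 8),
                               group = 4L, sex = rep(c("M", "F"), 8),
                               row.names = colnames(counts))
    pb <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    de <- regionContrast(pb, 4L, "EC", "V1")
    typeI <- mean(de$p < 0.01, na.rm = TRUE)
    expect_gte(typeI, 0.005)
    expect_lte(typeI, 0.02)
})
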