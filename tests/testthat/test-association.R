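# Binomial group enrichment, donor-level Spearman correlation, binary
# covariate proportion tests, and marker-based cell-type annotation.

# minimal ClusterResult around given labels (no embedding needed here)
labelResult <- function(labs, donors = NULL) {
    counts <- matrix(rpois(30 * length(labs), 4) + 1L, 30, length(labs),
                     dimnames = list(sprintf("G%02d", 1:30), names(labs)))
    clusterResultFromLabels(labs, normalizeLog(counts), donors,
                            EmbeddingParams(nPCs = 3L))
}

test_that("binomial tail p matches exact pmf summation and flags follow both rules", {
    set.seed(8)
    # 10-cluster fixture over 4 groups
    labs <- setNames(sample(0:9, 2000, replace = TRUE,
                            prob = (10:1) / sum(10:1)),
                     sprintf("C%04d", 1:2000))
    groups <- setNames(sample(as.character(1:4), 2000, replace = TRUE,
                              prob = c(.4, .3, .2, .1)), names(labs))
    res <- labelResult(labs)
    enr <- binomialEnrichment(res, groups)
    p0 <- table(groups) / length(groups)
    for (i in seq_len(nrow(enr))) {
        x <- enr$observed[i]; n <- enr$size[i]; q <- p0[[enr$group[i]]]
        # exact pmf summation oracle
        pExact <- sum(dbinom(x:n, n, q))
        expect_equal(enr$p[i], pExact, tolerance = 1e-12)
    }
    # x/n = p0 exactly -> ratio 1, not enriched
    labs2 <- setNames(rep(0:1, each = 100), sprintf("B%03d", 1:200))
    groups2 <- setNames(rep(rep(c("1", "2"), each = 50), 2), names(labs2))
    enr2 <- binomialEnrichment(labelResult(labs2), groups2)
    expect_true(all(abs(enr2$ratio - 1) < 1e-12))
    expect_false(any(enr2$enriched))
})

test_that("a pure cluster from a 25% group reaches the 0.25^n tail", {
    # pure-g1 cluster of 100 nuclei; overall g1 share is 100/400 = 0.25
    # (size-ordered relabelling puts the 300-nucleus cluster at label 0)
    labs <- setNames(rep(0:1, c(100, 300)), sprintf("C%03d", 1:400))
    groups <- setNames(c(rep("g1", 100), rep(c("g2", "g3", "g4"), 100)),
                       names(labs))
    enr <- binomialEnrichment(labelResult(labs), groups)
    row <- enr[enr$cluster == 1 & enr$group == "g1", ]
    expect_equal(row$p, 0.25^100, tolerance = 1e-12)
    expect_true(row$enriched)
})

test_that("sub-threshold enrichment is rejected regardless of its p-value", {
    # cluster share 9% above expectation with an astronomically small p:
    # large cluster, p0 = 0.5, observed 54.5%
    n <- 20000L
    labs <- setNames(rep(0:1, each = n / 2), sprintf("C%05d", seq_len(n)))
    g <- rep("b", n)
    g[seq_len(n / 2)][seq_len(5450)] <- "a"            # cluster 0: 54.5% a
    g[(n / 2 + 1):n][seq_len(4550)] <- "a"             # overall: 50% a
    groups <- setNames(g, names(labs))
    enr <- binomialEnrichment(labelResult(labs), groups, alpha = 0.001,
                              minEnrich = 0.10)
    row <- enr[enr$cluster == 0 & enr$group == "a", ]
    expect_lt(row$padj, 1e-8)
    expect_false(row$enriched)          # 0.545 < 1.1 * 0.5
    expect_lt(row$ratio, 1.10)
})

test_that("Spearman p is exact at small n and matches an enumeration oracle", {
    x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8)   # n = 8, no ties
    y <- c(2, 0.5, 5, 1.0, 7, 3.0, 6.0, 9.0)
    st <- spearmanTest(x, y)
    expect_identical(st$method, "exact")
    # oracle: enumerate all 8! permutations with plain cor()
    perms <- myeloidStates:::permuteAll(8L)
    rx <- rank(x)
    rhoNull <- apply(perms, 1, function(p) cor(rx, rank(y)[p]))
    expect_equal(st$rho, cor(rank(x), rank(y)))
    expect_equal(st$p, mean(abs(rhoNull) >= abs(st$rho) - 1e-12))
    # strictly monotone pair: rho = 1, p = permutation mass at |rho| = 1
    stm <- spearmanTest(1:8, (1:8)^2)
    expect_equal(stm$rho, 1)
    expect_equal(stm$p, mean(abs(rhoNull2 <- 1 - 6 *
        rowSums(sweep(perms, 2, 1:8)^2) / (8 * 63)) >= 1 - 1e-12))
    # large n switches to the t approximation and tracks cor.test
    set.seed(2); xa <- rnorm(30); ya <- xa + rnorm(30)
    sta <- spearmanTest(xa, ya)
    ct <- suppressWarnings(cor.test(xa, ya, method = "spearman"))
    expect_identical(sta$method, "t-approximation")
    expect_equal(sta$rho, unname(ct$estimate))
})

test_that("proportion correlation recovers a planted monotone relation", {
    donors <- sprintf("D%02d", 1:8)
    # donor proportions strictly increasing with the readout
    nPer <- 200L
    propIn <- seq(0.05, 0.40, length.out = 8)
    labs <- c(); dn <- c()
    for (i in 1:8) {
        nIn <- round(nPer * propIn[i])
        labs <- c(labs, rep(1L, nIn), rep(0L, nPer - nIn))
        dn <- c(dn, rep(donors[i], nPer))
    }
    names(labs) <- sprintf("C%04d", seq_along(labs))
    dnN <- setNames(dn, names(labs))
    res <- labelResult(labs, dnN)
    meta <- data.frame(donor = dnN, row.names = names(labs))
    readouts <- data.frame(donor = donors, ptau_ratio = exp(propIn))
    pc <- proportionCorrelation(res, meta, readouts, assays = "ptau_ratio")
    # the planted cluster (relabelled by size to 1) has rho = 1 with the
    # exact two-sided enumeration p at n = 8
    row <- pc[pc$cluster == 1, ]
    expect_equal(row$rho, 1)
    expect_equal(row$p, 2 / factorial(8), tolerance = 1e-12)
    expect_true(row$significant)
})

test_that("degenerate proportions give NA correlation", {
    donors <- sprintf("D%02d", 1:8)
    labs <- setNames(rep(0L, 800), sprintf("C%04d", 1:800))
    dn <- setNames(rep(donors, each = 100), names(labs))
    res <- labelResult(labs, dn)
    meta <- data.frame(donor = dn, row.names = names(labs))
    readouts <- data.frame(donor = donors, ptau_ratio = 1:8)
    pc <- proportionCorrelation(res, meta, readouts, assays = "ptau_ratio")
    expect_true(is.na(pc$rho))
})

test_that("covariate proportion test matches the 2x2 continuity-corrected chi-square", {
    # 2x2 table (40/60 vs 10/90), n = 200
    labs <- setNames(rep(0:1, each = 100), sprintf("C%03d", 1:200))
    cov <- setNames(c(rep(TRUE, 40), rep(FALSE, 60),
                      rep(TRUE, 10), rep(FALSE, 90)), names(labs))
    out <- covariateProportionTest(labelResult(labs), cov)
    # hand-computed Yates chi-square for (40,60 | 10,90)
    o <- matrix(c(40, 60, 10, 90), 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    chi <- sum((abs(o - e) - 0.5)^2 / e)
    pHand <- pchisq(chi, 1, lower.tail = FALSE)
    expect_equal(out$p[out$cluster == 0], pHand, tolerance = 1e-12)
    # identical shares -> p ~ 1
    cov2 <- setNames(rep(c(TRUE, FALSE), 100), names(labs))
    out2 <- covariateProportionTest(labelResult(labs), cov2)
    expect_true(all(out2$p >= 0.99))
    expect_error(covariateProportionTest(labelResult(labs),
                                         setNames(rep(TRUE, 200), names(labs))),
                 "both levels")
})

test_that("null covariates stay null after adjustment across runs", {
    set.seed(33)
    hits <- 0L
    for (r in 1:20) {
        labs <- setNames(sample(0:4, 600, replace = TRUE),
                         sprintf("C%03d", 1:600))
        cov <- setNames(sample(c(TRUE, FALSE), 600, replace = TRUE),
                        names(labs))
        out <- covariateProportionTest(labelResult(labs), cov)
        if (any(out$padj < 0.05, na.rm = TRUE)) hits <- hits + 1L
    }
    expect_lte(hits, 2L)
})

test_that("cell-type annotation follows the marker precedence rules", {
    cfg <- smallConfig(seed = 81L, nucleiPerSample = 12L, nGenes = 200L)
    sce <- simPair(cfg)$sce
    sce <- sce[, sce$is_myeloid]
    norm <- normalizeLog(SummarizedExperiment::assay(sce, "counts"))
    res <- truthClusters(sce, norm)
    ann <- annotateCellTypes(res, norm)
    # map truth names to relabelled ids via composition
    labs <- clusterLabels(res)
    for (cl in unique(labs)) {
        truthName <- names(which.max(table(sce$true_cluster[match(
            names(labs)[labs == cl], colnames(sce))])))
        expected <- switch(truthName, PvM = "PvM", Mono = "monocyte",
                           "microglia")
        expect_identical(unname(ann[as.character(cl)]), expected)
    }
    # all-zero marker expression -> microglia everywhere
    m0 <- matrix(rpois(40 * 60, 3) + 1L, 40, 60,
                 dimnames = list(sprintf("G%02d", 1:40),
                                 sprintf("C%02d", 1:60)))
    res0 <- clusterResultFromLabels(
        setNames(rep(0:1, each = 30), colnames(m0)), normalizeLog(m0),
        params = EmbeddingParams(nPCs = 3L))
    expect_true(all(annotateCellTypes(res0, normalizeLog(m0)) == "microglia"))
})

test_that("PvM outranks monocyte when both panels are elevated", {
    # construct 2 clusters; cluster A has both CCR2 and the PvM panel high,
    # PvM higher -> labelled PvM by precedence
    genes <- c("LYVE1", "MRC1", "CD163", "F13A1", "CCR2",
               sprintf("G%02d", 1:20))
    n <- 80L
    m <- matrix(rpois(25 * n, 3) + 1L, 25, n,
                dimnames = list(genes, sprintf("C%02d", 1:n)))
    m[1:4, 1:40] <- m[1:4, 1:40] + 60L      # PvM panel very high in A
    m[5, 1:40] <- m[5, 1:40] + 30L          # CCR2 also high in A
    labs <- setNames(rep(0:1, each = 40), colnames(m))
    res <- clusterResultFromLabels(labs, normalizeLog(m),
                                   params = EmbeddingParams(nPCs = 3L))
    ann <- annotateCellTypes(res, normalizeLog(m))
    expect_identical(unname(ann[names(ann) ==
        as.character(clusterLabels(res)[["C01"]])]), "PvM")
})
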