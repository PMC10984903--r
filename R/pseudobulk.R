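# Pseudobulk aggregation, NB region contrasts with sex adjustment and
# control-group filtering, gene-program k-means over regional profiles,
# transition tracking, readout correlation and early-reversal genes.

#' Sum-aggregate counts to sample level
#'
#' Exact integer column sums of the nucleus matrix within each sample.
#'
#' @param counts Gene x nucleus count matrix.
#' @param meta data.frame/DataFrame with rownames = barcodes and columns
#'   \code{sample}, \code{donor}, \code{region}, \code{group} (and
#'   optionally \code{sex}).
#' @return A \code{SummarizedExperiment} with a \code{counts} assay
#'   (gene x sample) and per-sample colData.
#' @export
pseudobulk <- function(counts, meta) {
    meta <- as.data.frame(meta)[colnames(counts), , drop = FALSE]
    if (anyNA(meta$sample)) stop("every nucleus must map to a sample")
    samples <- sort(unique(meta$sample))
    ind <- Matrix::sparseMatrix(i = seq_len(ncol(counts)),
                                j = match(meta$sample, samples),
                                x = 1,
                                dims = c(ncol(counts), length(samples)))
    pb <- as.matrix(counts %*% ind)
    storage.mode(pb) <- "integer"
    colnames(pb) <- samples
    rownames(pb) <- rownames(counts)
    first <- match(samples, meta$sample)
    cd <- S4Vectors::DataFrame(
        sample = samples,
        donor = meta$donor[first], region = meta$region[first],
        group = meta$group[first],
        sex = if ("sex" %in% colnames(meta)) meta$sex[first] else "unknown",
        nNuclei = as.integer(Matrix::colSums(ind)),
        row.names = samples)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = pb), colData = cd)
}

# trimmed-mean-of-log-ratios normalisation factors (reference = sample
# whose library size is closest to the median), scaled to geometric mean 1
.tmmFactors <- function(pb, trim = 0.3) {
    lib <- colSums(pb)
    ref <- which.min(abs(lib - median(lib)))
    f <- vapply(seq_len(ncol(pb)), function(j) {
        ok <- pb[, j] > 0 & pb[, ref] > 0
        if (!any(ok)) return(1)
        lr <- log((pb[ok, j] / lib[j]) / (pb[ok, ref] / lib[ref]))
        exp(mean(lr, trim = trim))
    }, numeric(1))
    f / exp(mean(log(f)))
}

# NB (log link) IRLS with fixed dispersion phi; phi = 0 is Poisson.
# Returns beta, se (Wald, from expected information), fitted mu.
.nbFit <- function(X, y, offset, phi) {
    beta <- qr.coef(qr(X), log(pmax(y, 0.5)) - offset)
    beta[is.na(beta)] <- 0
    for (it in 1:50) {
        eta <- drop(X %*% beta) + offset
        mu <- pmax(exp(eta), 1e-10)
        w <- mu / (1 + phi * mu)
        z <- (eta - offset) + (y - mu) / mu
        XtW <- crossprod(X, X * w)
        betaNew <- tryCatch(solve(XtW, crossprod(X, w * z)),
                            error = function(e) beta)
        if (max(abs(betaNew - beta)) < 1e-10) { beta <- betaNew; break }
        beta <- betaNew
    }
    eta <- drop(X %*% beta) + offset
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + phi * mu)
    cov <- tryCatch(solve(crossprod(X, X * w)),
                    error = function(e) matrix(NA, ncol(X), ncol(X)))
    list(beta = drop(beta), se = sqrt(diag(cov)), mu = mu)
}

#' Negative-binomial region contrast on pseudobulk samples
#'
#' Within one pathology group, tests each gene for differential expression
#' between two regions with a log-link negative-binomial GLM
#' (design: region + sex, library-size offsets from trimmed-mean
#' normalisation factors). Gene-wise dispersions are estimated by method
#' of moments from Poisson residuals and shrunk toward the global median;
#' the region coefficient is tested by a Wald z-test. A gene is a DEG when
#' nominal p < \code{pThresh} and |log2FC| > \code{lfcThresh}.
#'
#' @param pb Output of [pseudobulk()].
#' @param group Pathology group to subset.
#' @param regionA,regionB Regions to contrast (log2FC is A relative to B).
#' @param adjustSex Include sex in the design (default TRUE).
#' @param pThresh,lfcThresh DEG filters (defaults 0.01 and 1.2).
#' @param dispersion Optional fixed dispersion for all genes (0 gives a
#'   Poisson fit); default NULL estimates per gene.
#' @param minSamples Minimum samples per region (default 3).
#' @param priorN Shrinkage weight toward the global dispersion
#'   (default 10 pseudo-samples).
#' @return data.frame: gene, log2FC, p, padj, deg, dispersion.
#' @export
regionContrast <- function(pb, group, regionA, regionB, adjustSex = TRUE,
                           pThresh = 0.01, lfcThresh = 1.2,
                           dispersion = NULL, minSamples = 3L,
                           priorN = 10) {
    cd <- SummarizedExperiment::colData(pb)
    sel <- cd$group == group & cd$region %in% c(regionA, regionB)
    cd <- cd[sel, , drop = FALSE]
    y <- SummarizedExperiment::assay(pb, "counts")[, sel, drop = FALSE]
    nA <- sum(cd$region == regionA); nB <- sum(cd$region == regionB)
    if (nA < minSamples || nB < minSamples)
        stop("need >= ", minSamples, " samples per region within the group")
    X <- cbind(`(Intercept)` = 1,
               region = as.numeric(cd$region == regionA))
    if (adjustSex && length(unique(cd$sex)) > 1) {
        Xs <- cbind(X, sex = as.numeric(cd$sex == sort(unique(cd$sex))[1]))
        if (qr(Xs)$rank < ncol(Xs))
            stop("region is confounded with sex in group ", group)
        X <- Xs
    }
    lib <- colSums(y)
    offset <- log(lib * .tmmFactors(y))

    # method-of-moments dispersion from Poisson fits, shrunk to the median
    estPhi <- is.null(dispersion)
    n <- nrow(X); pDesign <- ncol(X)
    phiGene <- if (estPhi) {
        # method-of-moments from Poisson residuals with a df correction
        # (fitted means absorb p of the n residual directions)
        raw <- vapply(seq_len(nrow(y)), function(gi) {
            yi <- y[gi, ]
            if (sum(yi) == 0) return(NA_real_)
            f <- .nbFit(X, yi, offset, 0)
            max(0, sum((yi - f$mu)^2 - f$mu) /
                   ((1 - pDesign / n) * sum(f$mu^2)))
        }, numeric(1))
        glob <- median(raw, na.rm = TRUE)
        (n * ifelse(is.na(raw), glob, raw) + priorN * glob) / (n + priorN)
    } else rep(dispersion, nrow(y))

    # Wald statistic referred to a t distribution on the residual df
    # (small-sample guard; identical to the normal reference as n grows,
    # and to the Poisson GLM z-test when a dispersion of 0 is supplied)
    res <- vapply(seq_len(nrow(y)), function(gi) {
        yi <- y[gi, ]
        if (sum(yi) == 0) return(c(NA_real_, NA_real_))
        f <- .nbFit(X, yi, offset, phiGene[gi])
        zstat <- f$beta["region"] / f$se[2]
        p <- if (estPhi) 2 * pt(-abs(zstat), df = n - pDesign)
             else 2 * pnorm(-abs(zstat))
        c(f$beta["region"] / log(2), p)
    }, numeric(2))
    out <- data.frame(gene = rownames(y), log2FC = res[1, ], p = res[2, ],
                      dispersion = phiGene, row.names = NULL)
    out$padj <- p.adjust(out$p, method = "BH")
    out$deg <- !is.na(out$p) & out$p < pThresh & abs(out$log2FC) > lfcThresh
    out
}

#' Filter out genes with regional differences in the control group
#'
#' Drops from a disease-group contrast the genes whose same-contrast
#' p-value in the pathology-group-1 (control) table falls below
#' \code{pCtrl}; genes absent from the control table are retained with an
#' NA control p.
#'
#' @param deDisease,deControl DE tables from [regionContrast()].
#' @param pCtrl Control significance cutoff (default 0.05).
#' @return The disease table with \code{pControl} and \code{dropped}
#'   columns; dropped genes removed, and reported in attribute
#'   \code{"dropped"}.
#' @export
controlFilter <- function(deDisease, deControl, pCtrl = 0.05) {
    m <- match(deDisease$gene, deControl$gene)
    if (anyNA(m))
        warning(sum(is.na(m)), " gene(s) missing from the control table; ",
                "retained with NA control p")
    pc <- deControl$p[m]
    drop <- !is.na(pc) & pc < pCtrl
    out <- deDisease
    out$pControl <- pc
    dropped <- out$gene[drop]
    out <- out[!drop, , drop = FALSE]
    attr(out, "dropped") <- dropped
    out
}

# seeded Lloyd k-means with restarts; objective asserted non-increasing
# within every restart
.lloyd <- function(Z, k, nInit, maxIter, seed) {
    set.seed(seed)
    best <- NULL
    n <- nrow(Z)
    for (r in seq_len(nInit)) {
        cent <- Z[sample(n, k), , drop = FALSE]
        lastObj <- Inf
        lab <- NULL
        for (it in seq_len(maxIter)) {
            d2 <- outer(rowSums(Z^2), rowSums(cent^2), `+`) -
                2 * tcrossprod(Z, cent)
            lab <- max.col(-d2, ties.method = "first")
            obj <- sum(d2[cbind(seq_len(n), lab)])
            stopifnot(obj <= lastObj + 1e-8)
            if (lastObj - obj < 1e-12) { lastObj <- obj; break }
            lastObj <- obj
            for (j in seq_len(k)) {
                if (any(lab == j))
                    cent[j, ] <- colMeans(Z[lab == j, , drop = FALSE])
                else cent[j, ] <- Z[sample(n, 1), ]
            }
        }
        # final assignment objective (after the last centroid update)
        d2 <- outer(rowSums(Z^2), rowSums(cent^2), `+`) - 2 * tcrossprod(Z, cent)
        lab <- max.col(-d2, ties.method = "first")
        obj <- sum(d2[cbind(seq_len(n), lab)])
        if (is.null(best) || obj < best$obj)
            best <- list(obj = obj, labels = lab, centers = cent)
    }
    best
}

#' K-means clustering of regional gene-expression programs
#'
#' Within one pathology group, each gene's counts are summed per region,
#' z-scored across the ordered region panel, and clustered by seeded
#' k-means (50 random restarts of at most 15 Lloyd iterations per k). The
#' within-cluster sum of squares is recorded for k = 1..10 and the number
#' of clusters is chosen at the elbow: the k with the largest positive
#' second difference of the WSS curve (falling back to 2 with a warning
#' when no second difference is positive). Genes with zero or constant
#' regional sums are excluded before z-scoring.
#'
#' @param pb Output of [pseudobulk()].
#' @param group Pathology group.
#' @param kRange Candidate k values (default 1:10).
#' @param nInit,maxIter Restarts and Lloyd iterations (defaults 50, 15).
#' @param seed RNG seed.
#' @param k Optional fixed k, bypassing the elbow rule.
#' @param genes Optional gene subset.
#' @return A [GeneClusterResult-class].
#' @export
kmeansProfiles <- function(pb, group, kRange = 1:10, nInit = 50L,
                           maxIter = 15L, seed = 0L, k = NULL,
                           genes = NULL) {
    cd <- SummarizedExperiment::colData(pb)
    sel <- cd$group == group
    y <- SummarizedExperiment::assay(pb, "counts")[, sel, drop = FALSE]
    if (!is.null(genes)) y <- y[genes, , drop = FALSE]
    regions <- unique(as.character(cd$region[sel]))
    if (length(regions) < 2) stop("need the full region panel for the group")
    prof <- vapply(regions, function(r)
        rowSums(y[, cd$region[sel] == r, drop = FALSE]), numeric(nrow(y)))
    keep <- apply(prof, 1, function(p) sd(p) > 0)
    prof <- prof[keep, , drop = FALSE]
    Z <- t(scale(t(prof)))
    # scale() uses the n-1 sd; profiles keep mean 0, sd 1 per gene
    wss <- vapply(kRange, function(kk)
        .lloyd(Z, kk, nInit, maxIter, seed + kk)$obj, numeric(1))
    if (is.null(k)) {
        if (length(kRange) >= 3) {
            inner <- 2:(length(kRange) - 1)
            d2 <- wss[inner - 1] - 2 * wss[inner] + wss[inner + 1]
            if (any(d2 > 0)) k <- kRange[inner][which.max(d2)]
            else { warning("no positive second difference; using k = 2"); k <- 2L }
        } else k <- kRange[which.min(wss)]
    }
    fit <- .lloyd(Z, k, nInit, maxIter, seed + k)
    new("GeneClusterResult", group = as.character(group),
        k = as.integer(k),
        labels = setNames(as.integer(fit$labels), rownames(Z)),
        centroids = fit$centers, profiles = Z,
        wss = setNames(wss, kRange))
}

#' Gene-cluster transitions between pathology groups
#'
#' Contingency counts of (cluster in group g, cluster in group h) over the
#' shared gene universe, with row percentages and a JSON Sankey export
#' (nodes/links).
#'
#' @param resG,resH [GeneClusterResult-class] objects for consecutive
#'   groups.
#' @return list: \code{counts}, \code{percent} (rows sum to 100),
#'   \code{json} (Sankey nodes/links as a JSON string).
#' @export
clusterTransitions <- function(resG, resH) {
    shared <- intersect(names(resG@labels), names(resH@labels))
    if (length(shared) == 0L) stop("disjoint gene universes")
    tab <- table(from = resG@labels[shared], to = resH@labels[shared])
    cnt <- matrix(as.integer(tab), nrow = nrow(tab),
                  dimnames = dimnames(tab))
    pct <- sweep(cnt, 1, pmax(rowSums(cnt), 1L), `/`) * 100
    nodes <- c(paste0("g", resG@group, "_c", rownames(cnt)),
               paste0("g", resH@group, "_c", colnames(cnt)))
    links <- which(cnt > 0, arr.ind = TRUE)
    json <- jsonlite::toJSON(list(
        nodes = data.frame(name = nodes),
        links = data.frame(source = links[, 1] - 1L,
                           target = nrow(cnt) + links[, 2] - 1L,
                           value = cnt[links])), dataframe = "rows")
    list(counts = cnt, percent = pct, json = json)
}

#' Correlate gene-cluster expression with biochemical readouts
#'
#' Per gene cluster, the cluster score of a sample is the mean z-scored
#' (across the group's samples) log1p-CPM of the cluster's genes; scores
#' are Spearman-correlated with each readout over the group's samples.
#'
#' @param res A [GeneClusterResult-class].
#' @param pb The [pseudobulk()] object it was built from.
#' @param readouts Readout table with a \code{sample} column.
#' @param assays Assay columns (default: the four study assays present).
#' @return data.frame: cluster, assay, rho, p (NA with < 4 samples).
#' @export
profileReadoutCorrelation <- function(res, pb, readouts, assays = NULL) {
    if (is.null(assays))
        assays <- intersect(c("ptau_ratio", "ht7_tau", "hek_seeding",
                              "ab_3d6"), colnames(readouts))
    cd <- SummarizedExperiment::colData(pb)
    sel <- which(cd$group == res@group)
    full <- SummarizedExperiment::assay(pb, "counts")[, sel, drop = FALSE]
    y <- full[names(res@labels), , drop = FALSE]
    cpm <- log1p(sweep(y, 2, colSums(full) / 1e6, `/`))
    Z <- t(scale(t(cpm)))
    Z[is.na(Z)] <- 0
    rows <- list()
    for (cl in sort(unique(res@labels))) {
        score <- colMeans(Z[res@labels == cl, , drop = FALSE])
        for (a in assays) {
            r <- readouts[[a]][match(colnames(y), readouts$sample)]
            if (sum(is.finite(r)) < 4) {
                st <- list(rho = NA_real_, p = NA_real_)
            } else st <- spearmanTest(score, r)
            rows[[length(rows) + 1L]] <- data.frame(
                cluster = cl, assay = a, rho = st$rho, p = st$p)
        }
    }
    do.call(rbind, rows)
}

#' Genes with opposite regional profiles in early disease
#'
#' Flags genes whose z-scored regional profile in one pathology group is
#' anti-correlated (Pearson r at or below \code{threshold}) with their
#' profile in the next group — the early-reversal pattern. Output is
#' sorted by correlation, most reversed first.
#'
#' @param resG1,resG2 [GeneClusterResult-class] objects of the two groups.
#' @param threshold Correlation cutoff (default -0.5).
#' @return data.frame: gene, correlation, flagged (sorted ascending).
#' @export
earlyReversalGenes <- function(resG1, resG2, threshold = -0.5) {
    shared <- intersect(rownames(resG1@profiles), rownames(resG2@profiles))
    if (length(shared) == 0L) stop("no shared genes between the groups")
    r <- vapply(shared, function(g)
        cor(resG1@profiles[g, ], resG2@profiles[g, ]), numeric(1))
    out <- data.frame(gene = shared, correlation = r,
                      flagged = r <= threshold, row.names = NULL)
    out[order(out$correlation), , drop = FALSE]
}
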