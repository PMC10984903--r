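# Cluster-pathology association: binomial group enrichment, donor-level
# Spearman correlation of cluster proportions with biochemical readouts,
# binary-covariate proportion tests, and marker-based cell-type annotation.

# Spearman rho with exact permutation p for n <= 9 (no ties), t
# approximation otherwise. Exact null distributions of rho are enumerated
# once per n and cached.
.spearmanNullEnv <- new.env(parent = emptyenv())

.spearmanNull <- function(n) {
    key <- as.character(n)
    if (!is.null(.spearmanNullEnv[[key]])) return(.spearmanNullEnv[[key]])
    perms <- permuteAll(n)
    d2 <- rowSums(sweep(perms, 2, seq_len(n))^2)
    rhos <- 1 - 6 * d2 / (n * (n^2 - 1))
    .spearmanNullEnv[[key]] <- rhos
    rhos
}

# matrix of all permutations of 1..n (n <= 9), one per row
permuteAll <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- permuteAll(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(pos) {
        if (pos == 1L) cbind(n, sub)
        else if (pos == n) cbind(sub, n)
        else cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, pos:(n - 1L), drop = FALSE])
    }))
}

#' Spearman correlation test
#'
#' Rank correlation with a two-sided p-value: exact (full permutation
#' enumeration) for n <= 9 without ties, t approximation otherwise.
#'
#' @param x,y Numeric vectors.
#' @return list(rho, p, method).
#' @export
spearmanTest <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3 || sd(x) == 0 || sd(y) == 0)
        return(list(rho = NA_real_, p = NA_real_, method = "undefined"))
    rho <- cor(rank(x), rank(y))
    ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
    if (n <= 9 && !ties) {
        null <- .spearmanNull(n)
        p <- mean(abs(null) >= abs(rho) - 1e-12)
        method <- "exact"
    } else {
        tt <- rho * sqrt((n - 2) / (1 - rho^2 + 1e-300))
        p <- 2 * pt(-abs(tt), df = n - 2)
        method <- "t-approximation"
    }
    list(rho = rho, p = min(p, 1), method = method)
}

#' Binomial enrichment of pathology groups per cluster
#'
#' For each cluster c and group g, tests whether the cluster holds more
#' group-g nuclei than expected from g's overall share p0 (one-sided
#' binomial tail P(X >= x) with X ~ Bin(cluster size, p0)). p-values are
#' BH-adjusted across all cluster x group tests; a cluster is flagged
#' enriched when adjusted p < \code{alpha} and the observed proportion
#' exceeds p0 by at least \code{minEnrich} (x/n >= (1 + minEnrich) * p0).
#' Donor-specific clusters are excluded.
#'
#' @param result A [ClusterResult-class].
#' @param groups Named vector, pathology group per barcode.
#' @param alpha Adjusted-p threshold (default 0.001).
#' @param minEnrich Minimum relative enrichment (default 0.10).
#' @return data.frame with cluster, group, observed, size, expected
#'   proportion, obs/exp ratio, p, adjusted p and enriched flag.
#' @export
binomialEnrichment <- function(result, groups, alpha = 0.001,
                               minEnrich = 0.10) {
    labs <- result@labels[!result@labels %in%
                          (which(result@donorSpecific) - 1L)]
    groups <- groups[names(labs)]
    if (length(unique(groups)) < 2) stop("need >= 2 groups")
    p0 <- table(groups) / length(groups)
    rows <- list()
    for (cl in sort(unique(labs))) {
        inCl <- groups[labs == cl]
        n <- length(inCl)
        if (n == 0L) { warning("empty cluster ", cl, " skipped"); next }
        for (g in names(p0)) {
            x <- sum(inCl == g)
            p <- pbinom(x - 1L, n, p0[[g]], lower.tail = FALSE)
            rows[[length(rows) + 1L]] <- data.frame(
                cluster = cl, group = g, observed = x, size = n,
                expected = p0[[g]], ratio = (x / n) / p0[[g]], p = p,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$padj <- p.adjust(out$p, method = "BH")
    out$enriched <- out$padj < alpha &
        (out$observed / out$size) >= (1 + minEnrich) * out$expected
    out
}

#' Donor-level correlation of cluster proportions with readouts
#'
#' Per donor, the normalised proportion is the donor's nuclei in the
#' cluster divided by the donor's total nuclei in the dataset. Each
#' cluster's proportions are Spearman-correlated with each biochemical
#' readout for the corresponding donor x region sample; significance is
#' declared at nominal p < \code{alpha}. Donor-specific clusters are
#' excluded; constant proportions give NA.
#'
#' @param result A [ClusterResult-class].
#' @param meta data.frame/DataFrame with \code{donor} per barcode
#'   (rownames barcodes).
#' @param readouts Readout table with \code{donor} and assay columns; one
#'   row per donor (pass a single region's rows for region-level analysis).
#' @param assays Assay column names (default the four study assays present).
#' @param alpha Nominal threshold (default 0.05).
#' @return data.frame: cluster, assay, rho, p, significant, direction.
#' @export
proportionCorrelation <- function(result, meta, readouts,
                                  assays = NULL, alpha = 0.05) {
    if (is.null(assays))
        assays <- intersect(c("ptau_ratio", "ht7_tau", "hek_seeding",
                              "ab_3d6"), colnames(readouts))
    labs <- result@labels[!result@labels %in%
                          (which(result@donorSpecific) - 1L)]
    donor <- meta[names(labs), "donor"]
    donors <- sort(unique(donor))
    if (length(donors) < 5) stop("need >= 5 donors with nuclei")
    if (anyDuplicated(readouts$donor))
        stop("readouts must have one row per donor; subset to one region")
    total <- table(factor(donor, levels = donors))
    rows <- list()
    for (cl in sort(unique(labs))) {
        inCl <- table(factor(donor[labs == cl], levels = donors))
        prop <- as.numeric(inCl) / as.numeric(total)
        for (a in assays) {
            r <- readouts[[a]][match(donors, readouts$donor)]
            st <- spearmanTest(prop, r)
            rows[[length(rows) + 1L]] <- data.frame(
                cluster = cl, assay = a, rho = st$rho, p = st$p,
                significant = !is.na(st$p) && st$p < alpha,
                direction = if (is.na(st$rho)) NA_character_
                            else if (st$rho >= 0) "positive" else "negative",
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' Per-cluster proportion test for a binary covariate
#'
#' For each cluster, compares the covariate-positive share inside the
#' cluster with the share in its complement by a chi-square test with
#' continuity correction on the 2 x 2 table, BH-adjusted across clusters.
#'
#' @param result A [ClusterResult-class].
#' @param covariate Named logical per barcode.
#' @return data.frame: cluster, share inside/outside, p, padj.
#' @export
covariateProportionTest <- function(result, covariate) {
    labs <- result@labels
    covariate <- covariate[names(labs)]
    if (length(unique(covariate)) < 2)
        stop("covariate must have both levels present")
    rows <- lapply(sort(unique(labs)), function(cl) {
        a <- covariate[labs == cl]; b <- covariate[labs != cl]
        tab <- rbind(c(sum(a), sum(!a)), c(sum(b), sum(!b)))
        p <- tryCatch(suppressWarnings(prop.test(tab)$p.value),
                      error = function(e) NA_real_)
        data.frame(cluster = cl, shareIn = mean(a), shareOut = mean(b),
                   p = p)
    })
    out <- do.call(rbind, rows)
    out$padj <- p.adjust(out$p, method = "BH")
    out
}

#' Annotate clusters as microglia, PvM or monocyte
#'
#' Per cluster, computes the mean z-scored log-normalised expression of the
#' perivascular-macrophage panel (LYVE1, MRC1, CD163, F13A1) and of the
#' monocyte marker CCR2. The cluster is PvM when its PvM panel mean is
#' above \code{threshold} and at least as high as its CCR2 score
#' (precedence), monocyte when CCR2 exceeds the threshold with the PvM
#' panel below it, otherwise microglia.
#'
#' @param result A [ClusterResult-class].
#' @param normalized Log-normalised matrix.
#' @param pvmMarkers,monoMarker Marker sets.
#' @param threshold Mean-z cutoff (default 0.5).
#' @return Named character, label per cluster.
#' @export
annotateCellTypes <- function(result, normalized,
                              pvmMarkers = c("LYVE1", "MRC1", "CD163",
                                             "F13A1"),
                              monoMarker = "CCR2", threshold = 0.5) {
    meanZ <- function(genes) {
        genes <- intersect(genes, rownames(normalized))
        if (length(genes) == 0L)
            return(setNames(rep(0, length(unique(result@labels))),
                            sort(unique(result@labels))))
        x <- as.matrix(normalized[genes, names(result@labels), drop = FALSE])
        mu <- rowMeans(x); sg <- apply(x, 1, sd); sg[sg == 0] <- 1
        z <- colMeans((x - mu) / sg)
        tapply(z, result@labels, mean)
    }
    pvm <- meanZ(pvmMarkers)
    mono <- meanZ(monoMarker)
    labels <- ifelse(pvm > threshold & pvm >= mono, "PvM",
                     ifelse(mono > threshold, "monocyte", "microglia"))
    setNames(labels, names(pvm))
}
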