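# Pathology binning, per-cluster density shifts across bins, and the
# two-part (hurdle) differential-expression test with donor/region
# covariates.

#' Bin a biochemical readout into equal-width classes
#'
#' Splits the observed range of one assay into \code{nBins} equal-width
#' intervals (low, low-medium, medium, medium-high, high for the default
#' 5). Assignment is half-open: a value exactly on an interior edge goes to
#' the higher bin; the last bin is right-closed. Bins to which fewer than
#' \code{minDonors} donors contribute are flagged invalid and excluded
#' from reporting downstream.
#'
#' @param readouts Sample readout table with \code{sample}, \code{donor}
#'   and assay columns.
#' @param assay Assay column to bin.
#' @param nBins Number of classes (default 5).
#' @param minDonors Minimum contributing donors per valid bin (default 3).
#' @param mode \code{"width"} (equal-width, default) or \code{"quantile"}
#'   (equal-frequency).
#' @return list: \code{assignment} (data.frame sample, donor, value, bin),
#'   \code{edges}, \code{donorsPerBin}, \code{valid} (logical per bin).
#' @export
binReadouts <- function(readouts, assay, nBins = 5L, minDonors = 3L,
                        mode = c("width", "quantile")) {
    mode <- match.arg(mode)
    x <- readouts[[assay]]
    if (is.null(x)) stop("assay not found: ", assay)
    if (length(unique(x)) < nBins)
        stop("need >= nBins distinct readout values")
    if (max(x) == min(x)) stop("constant readout cannot be binned")
    edges <- if (mode == "width") seq(min(x), max(x), length.out = nBins + 1L)
             else unique(quantile(x, probs = seq(0, 1, length.out = nBins + 1L)))
    bin <- findInterval(x, edges, rightmost.closed = TRUE)
    donorsPerBin <- vapply(seq_len(nBins), function(b)
        length(unique(readouts$donor[bin == b])), integer(1))
    list(assignment = data.frame(sample = readouts$sample,
                                 donor = readouts$donor,
                                 value = x, bin = bin,
                                 stringsAsFactors = FALSE),
         edges = edges, donorsPerBin = donorsPerBin,
         valid = donorsPerBin >= minDonors)
}

#' Per-cluster density shifts across pathology bins
#'
#' For each bin, the density of a cluster is the fraction of the bin's
#' nuclei assigned to it (densities sum to 1 within each bin). Sequential
#' differences are reported for each adjacent pair of valid bins
#' (low vs low-medium, low-medium vs medium, ...).
#'
#' @param result A [ClusterResult-class].
#' @param bins Output of [binReadouts()].
#' @param sampleOf Named character, sample per barcode.
#' @return list: \code{density} (bin x cluster matrix over valid bins;
#'   invalid bins dropped), \code{shifts} (data.frame fromBin, toBin,
#'   cluster, delta).
#' @export
densityShift <- function(result, bins, sampleOf) {
    labs <- result@labels
    sampleOf <- sampleOf[names(labs)]
    binOf <- bins$assignment$bin[match(sampleOf, bins$assignment$sample)]
    keep <- !is.na(binOf)
    tab <- table(bin = binOf[keep], cluster = labs[keep])
    dens <- sweep(tab, 1, rowSums(tab), `/`)
    stopifnot(all(abs(rowSums(dens) - 1) < 1e-12))
    validBins <- which(bins$valid)
    present <- intersect(as.character(validBins), rownames(dens))
    densV <- dens[present, , drop = FALSE]
    shifts <- NULL
    vb <- as.integer(present)
    if (length(vb) >= 2) {
        pairs <- cbind(vb[-length(vb)], vb[-1])
        shifts <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
            a <- as.character(pairs[i, 1]); b <- as.character(pairs[i, 2])
            data.frame(fromBin = pairs[i, 1], toBin = pairs[i, 2],
                       cluster = as.integer(colnames(densV)),
                       delta = as.numeric(densV[b, ] - densV[a, ]))
        }))
    }
    list(density = unclass(densV), shifts = shifts)
}

# binomial deviance via IRLS with optional ridge penalty (used as a
# fallback on separation; the same penalty is applied to full and null
# fits so the LRT stays comparable)
.binomDeviance <- function(X, y, ridge = 0) {
    fit <- NULL
    sep <- FALSE
    withCallingHandlers(
        fit <- glm.fit(X, y, family = binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    if (!sep && !is.null(fit)) return(list(dev = fit$deviance, separated = FALSE))
    # ridge IRLS fallback
    p <- ncol(X)
    beta <- rep(0, p)
    pen <- diag(ridge, p); pen[1, 1] <- 0
    for (it in 1:50) {
        eta <- drop(X %*% beta)
        mu <- 1 / (1 + exp(-eta))
        w <- pmax(mu * (1 - mu), 1e-10)
        z <- eta + (y - mu) / w
        betaNew <- tryCatch(
            solve(crossprod(X, X * w) + pen, crossprod(X, w * z)),
            error = function(e) beta)
        if (max(abs(betaNew - beta)) < 1e-8) { beta <- betaNew; break }
        beta <- betaNew
    }
    mu <- 1 / (1 + exp(-drop(X %*% beta)))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    list(dev = dev, separated = TRUE)
}

# pooled donor factor: donors with < minN nuclei in the comparison are
# merged into "other"
.poolDonors <- function(donor, minN = 5L) {
    tab <- table(donor)
    small <- names(tab)[tab < minN]
    donor[donor %in% small] <- "other"
    factor(donor)
}

#' Two-part hurdle differential expression
#'
#' For each gene, combines (i) a discrete component — likelihood-ratio
#' test of the group term in a logistic regression of detection
#' (count > 0) on group plus covariates — and (ii) a continuous component
#' — likelihood-ratio test of the group term in a linear model of
#' log-normalised expression among detected nuclei. The combined statistic
#' is the sum of the two chi-squares with summed degrees of freedom;
#' p-values are BH-adjusted across genes. Donor and region enter as
#' fixed-effect indicators (donors with < 5 nuclei pooled into "other").
#' log2FC is the difference in mean log2-normalised expression
#' (group A minus group B), and pct the detection fraction per side.
#'
#' On quasi-complete separation the logistic fit falls back to a
#' ridge-penalised IRLS (applied to full and null models alike) with a
#' warning. Genes detected in fewer than 2 nuclei on either side skip the
#' continuous part, with the df adjusted.
#'
#' @param normalized Log-normalised gene x nucleus matrix.
#' @param groupA,groupB Barcode vectors (each >= \code{minCells}).
#' @param covariates Optional data.frame (rownames barcodes) of factors,
#'   e.g. donor and region.
#' @param minCells Minimum nuclei per side (default 20).
#' @param genes Optional gene subset.
#' @return data.frame: gene, log2FC, chisqDiscrete, chisqContinuous,
#'   chisq, df, p, padj, pctA, pctB, separated.
#' @export
hurdleDE <- function(normalized, groupA, groupB, covariates = NULL,
                     minCells = 20L, genes = NULL) {
    if (length(groupA) < minCells || length(groupB) < minCells)
        stop("both groups need >= ", minCells, " nuclei")
    bc <- c(groupA, groupB)
    grp <- rep(c(1, 0), c(length(groupA), length(groupB)))
    X0 <- matrix(1, length(bc), 1, dimnames = list(NULL, "(Intercept)"))
    if (!is.null(covariates)) {
        cov <- covariates[bc, , drop = FALSE]
        for (cn in colnames(cov)) {
            v <- cov[[cn]]
            if (cn == "donor") v <- .poolDonors(as.character(v))
            f <- factor(v)
            if (nlevels(f) > 1)
                X0 <- cbind(X0, stats::model.matrix(~f)[, -1, drop = FALSE])
        }
    }
    X1 <- cbind(X0, group = grp)
    if (qr(X1)$rank < ncol(X1))
        stop("covariates are confounded with the group assignment")
    mat <- normalized[, bc, drop = FALSE]
    if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
    mat <- as.matrix(mat)
    det <- mat > 0
    nA <- length(groupA)
    ridge <- 1e-3 * length(bc)

    res <- lapply(seq_len(nrow(mat)), function(gi) {
        x <- as.numeric(mat[gi, ])
        d <- as.numeric(det[gi, ])
        sep <- FALSE
        if (var(d) == 0) {
            chiD <- 0; dfD <- 0L
        } else {
            f1 <- .binomDeviance(X1, d)
            if (f1$separated) {
                sep <- TRUE
                f1 <- .binomDeviance(X1, d, ridge)
                f0 <- .binomDeviance(X0, d, ridge)
            } else f0 <- .binomDeviance(X0, d)
            chiD <- max(0, f0$dev - f1$dev); dfD <- 1L
        }
        idx <- which(d > 0)
        nDetA <- sum(idx <= nA); nDetB <- sum(idx > nA)
        if (nDetA >= 2 && nDetB >= 2 && length(idx) > ncol(X1)) {
            xs <- x[idx]
            rss1 <- sum(lm.fit(X1[idx, , drop = FALSE], xs)$residuals^2)
            rss0 <- sum(lm.fit(X0[idx, , drop = FALSE], xs)$residuals^2)
            chiC <- length(idx) * log(max(rss0, 1e-300) / max(rss1, 1e-300))
            dfC <- 1L
        } else { chiC <- 0; dfC <- 0L }
        chi <- chiD + chiC; df <- dfD + dfC
        p <- if (df > 0) pchisq(chi, df, lower.tail = FALSE) else 1
        c(log2FC = (mean(x[seq_len(nA)]) - mean(x[-seq_len(nA)])) / log(2),
          chisqDiscrete = chiD, chisqContinuous = chiC, chisq = chi,
          df = df, p = p, pctA = mean(d[seq_len(nA)]),
          pctB = mean(d[-seq_len(nA)]), separated = as.numeric(sep))
    })
    out <- as.data.frame(do.call(rbind, res))
    out <- cbind(gene = rownames(mat), out)
    out$separated <- out$separated > 0
    if (any(out$separated))
        warning(sum(out$separated), " gene(s) hit separation; ",
                "ridge-penalised logistic fallback used")
    out$padj <- p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}

#' Per-cluster hurdle DE with the study's significance filters
#'
#' Runs [hurdleDE()] for each cluster with at least \code{minNuclei}
#' nuclei against the designated homeostatic cluster (or against every
#' other cluster pooled, with \code{reference = "rest"}). A gene is called
#' significant when adjusted p < \code{alphaAdj}, |log2FC| >
#' \code{lfcThresh}, and it is detected in at least \code{pctMin} of
#' nuclei on the upregulated side.
#'
#' @param normalized Log-normalised matrix.
#' @param result A [ClusterResult-class].
#' @param covariates Optional covariate data.frame (rownames barcodes).
#' @param reference \code{"homeostatic"} (compare to \code{homeostatic}
#'   cluster) or \code{"rest"}.
#' @param homeostatic Label of the homeostatic cluster (default 0).
#' @param minNuclei Minimum cluster size tested (default 100).
#' @param alphaAdj,lfcThresh,pctMin Significance filters (defaults 0.01,
#'   0.2, 0.10).
#' @return Named list of DE tables (one per tested cluster) with a
#'   \code{significant} column.
#' @export
clusterDE <- function(normalized, result, covariates = NULL,
                      reference = c("homeostatic", "rest"),
                      homeostatic = 0L, minNuclei = 100L,
                      alphaAdj = 0.01, lfcThresh = 0.2, pctMin = 0.10) {
    reference <- match.arg(reference)
    labs <- result@labels
    sizes <- table(labs)
    testable <- as.integer(names(sizes)[sizes >= minNuclei])
    out <- list()
    for (cl in setdiff(testable, if (reference == "homeostatic") homeostatic else integer())) {
        a <- names(labs)[labs == cl]
        b <- if (reference == "homeostatic") names(labs)[labs == homeostatic]
             else names(labs)[labs != cl]
        de <- hurdleDE(normalized, a, b, covariates)
        up <- ifelse(de$log2FC >= 0, de$pctA, de$pctB)
        de$significant <- de$padj < alphaAdj & abs(de$log2FC) > lfcThresh &
            up >= pctMin
        out[[as.character(cl)]] <- de
    }
    out
}
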