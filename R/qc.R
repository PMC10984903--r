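# Nucleus-level QC and marker-based myeloid subsetting.

#' Nucleus-level quality-control filter
#'
#' Applies, in fixed precedence order, the four absolute filters — exonic
#' read count > \code{minExonic}, mitochondrial fraction <
#' \code{maxMitoFraction}, detected genes >= \code{minGenes}, total UMIs >=
#' \code{minUMIs} — followed by the adaptive per-sample filter keeping only
#' nuclei whose log(detected genes) and log(total UMIs) lie within
#' median +/- \code{madMultiplier} * MAD of the sample's distribution.
#'
#' The MAD step uses the natural log and the unscaled median absolute
#' deviation (no 1.4826 consistency factor), computed once over the nuclei
#' that survive the four absolute filters; it is not iterated. Samples with
#' fewer than 3 surviving nuclei skip the MAD step with a warning. The
#' first failing rule (precedence: exonic, mito, genes, umis, mad) is
#' reported as the rejection reason.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{counts} assay and
#'   \code{colData} columns \code{exonic_counts}, \code{mito_fraction} and
#'   \code{sample}.
#' @param thresholds A [QCThresholds].
#' @return A list with \code{kept} (character, barcodes passing QC) and
#'   \code{report} (data.frame: barcode, sample, the QC statistics,
#'   \code{kept}, \code{reason} — \code{"pass"} for kept nuclei).
#' @export
qcFilter <- function(sce, thresholds = QCThresholds()) {
    stopifnot(is(thresholds, "QCThresholds"))
    validObject(thresholds)
    cd <- SummarizedExperiment::colData(sce)
    need <- c("exonic_counts", "mito_fraction", "sample")
    if (!all(need %in% colnames(cd)))
        stop("colData must contain: ", paste(need, collapse = ", "))
    counts <- SummarizedExperiment::assay(sce, "counts")
    genes <- Matrix::colSums(counts > 0)
    umis <- Matrix::colSums(counts)

    reason <- rep(NA_character_, ncol(sce))
    reason[is.na(reason) & !(cd$exonic_counts > thresholds@minExonic)] <- "exonic"
    reason[is.na(reason) & !(cd$mito_fraction < thresholds@maxMitoFraction)] <- "mito"
    reason[is.na(reason) & !(genes >= thresholds@minGenes)] <- "genes"
    reason[is.na(reason) & !(umis >= thresholds@minUMIs)] <- "umis"

    # adaptive per-sample filter over the survivors of the fixed filters
    surv <- is.na(reason)
    for (smp in unique(cd$sample)) {
        idx <- which(cd$sample == smp & surv)
        if (length(idx) == 0L) next
        if (length(idx) < 3L) {
            warning("sample ", smp, " has < 3 nuclei after fixed filters; ",
                    "MAD step skipped")
            next
        }
        for (stat in list(log(genes[idx]), log(umis[idx]))) {
            med <- median(stat)
            madv <- median(abs(stat - med))
            bad <- abs(stat - med) > thresholds@madMultiplier * madv
            reason[idx[bad & is.na(reason[idx])]] <- "mad"
        }
    }
    kept <- is.na(reason)
    reason[kept] <- "pass"
    report <- data.frame(
        barcode = colnames(sce), sample = cd$sample,
        exonic_counts = cd$exonic_counts, mito_fraction = cd$mito_fraction,
        detected_genes = as.integer(genes), total_umis = as.integer(umis),
        kept = kept, reason = reason, stringsAsFactors = FALSE)
    list(kept = colnames(sce)[kept], report = report)
}

#' Per-nucleus myeloid marker score
#'
#' Mean of z-scored log-normalised expression over the marker panel. Panel
#' genes absent from the matrix are dropped with a warning; genes with zero
#' variance contribute a z-score of 0.
#'
#' @param normalized Log-normalised gene x nucleus matrix (see
#'   [normalizeLog()]).
#' @param panel A [MarkerPanel].
#' @return Named numeric score per nucleus.
#' @export
myeloidScore <- function(normalized, panel = MarkerPanel()) {
    stopifnot(is(panel, "MarkerPanel"))
    present <- intersect(panel@markers, rownames(normalized))
    if (length(present) == 0L)
        stop("no panel gene detected in the matrix")
    if (length(present) < length(panel@markers))
        warning("panel genes missing from matrix: ",
                paste(setdiff(panel@markers, present), collapse = ", "))
    x <- as.matrix(normalized[present, , drop = FALSE])
    mu <- rowMeans(x)
    sg <- apply(x, 1, sd)
    z <- (x - mu) / ifelse(sg > 0, sg, 1)
    z[sg == 0, ] <- 0
    setNames(colMeans(z), colnames(normalized))
}

#' Subset nuclei by myeloid score
#'
#' Keeps barcodes with score >= \code{threshold} and reports the retained
#' fraction per region when region labels are supplied.
#'
#' @param scores Output of [myeloidScore()].
#' @param threshold Score cutoff (default from the panel is 0).
#' @param regions Optional named factor/character of region per barcode.
#' @return Character vector of retained barcodes; if \code{regions} is
#'   given, the per-region retained fraction is attached as attribute
#'   \code{"retainedFraction"}.
#' @export
subsetMyeloid <- function(scores, threshold = 0, regions = NULL) {
    stopifnot(all(is.finite(scores)))
    keep <- scores >= threshold
    if (!any(keep))
        stop("no nucleus passes the myeloid score threshold ", threshold,
             " (score range [", round(min(scores), 3), ", ",
             round(max(scores), 3), "])")
    out <- names(scores)[keep]
    if (!is.null(regions)) {
        regions <- regions[names(scores)]
        frac <- tapply(keep, regions, mean)
        attr(out, "retainedFraction") <- frac
    }
    out
}
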