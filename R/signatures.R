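# Public-signature comparison: fold-change Spearman correlation with
# detection/overlap filters, averaged signature expression per cluster,
# mouse-to-human symbol mapping, and hypergeometric over-representation.

#' Correlate a cluster's DE profile with a public signature
#'
#' Each side is filtered by its own rule first — the cluster DE table to
#' genes detected in at least \code{pctMin} of nuclei per comparison group
#' with adjusted p < \code{alphaFilter}; the signature by its configured
#' p-value type (adjusted for sc/sn and bulk studies, nominal for
#' laser-capture studies) below \code{alphaFilter} and, when it carries a
#' detection fraction, the same \code{pctMin} — then the two are joined on
#' gene symbol and the paired log2 fold changes are Spearman-correlated.
#' Fewer than \code{minOverlap} shared genes yields the insufficient-data
#' flag and no p-value.
#'
#' @param clusterDE data.frame with \code{gene}, \code{log2FC},
#'   \code{padj}, and detection fractions \code{pctA}/\code{pctB} (as
#'   produced by [hurdleDE()]).
#' @param signature data.frame with \code{gene}, \code{log2FC} and a
#'   p-value column (\code{padj} or \code{p}), optionally \code{pct}.
#' @param sigPType \code{"adjusted"} (default) or \code{"nominal"} —
#'   which signature p-value the filter uses.
#' @param minOverlap Minimum joined genes (default 10).
#' @param pctMin Detection filter (default 0.05).
#' @param alphaFilter Per-side significance filter (default 0.05).
#' @return list: rho, p, nOverlap, insufficient.
#' @export
signatureCorrelation <- function(clusterDE, signature,
                                 sigPType = c("adjusted", "nominal"),
                                 minOverlap = 10L, pctMin = 0.05,
                                 alphaFilter = 0.05) {
    sigPType <- match.arg(sigPType)
    a <- clusterDE
    if (all(c("pctA", "pctB") %in% colnames(a)))
        a <- a[pmax(a$pctA, a$pctB) >= pctMin, , drop = FALSE]
    if ("padj" %in% colnames(a))
        a <- a[!is.na(a$padj) & a$padj < alphaFilter, , drop = FALSE]
    b <- signature
    pcol <- if (sigPType == "adjusted" && "padj" %in% colnames(b)) "padj"
            else "p"
    if (pcol %in% colnames(b))
        b <- b[!is.na(b[[pcol]]) & b[[pcol]] < alphaFilter, , drop = FALSE]
    if ("pct" %in% colnames(b))
        b <- b[b$pct >= pctMin, , drop = FALSE]
    shared <- intersect(a$gene, b$gene)
    n <- length(shared)
    if (n < minOverlap)
        return(list(rho = NA_real_, p = NA_real_, nOverlap = n,
                    insufficient = TRUE))
    st <- spearmanTest(a$log2FC[match(shared, a$gene)],
                       b$log2FC[match(shared, b$gene)])
    list(rho = st$rho, p = st$p, nOverlap = n, insufficient = FALSE)
}

#' Averaged signature expression per cluster
#'
#' Mean of z-scored log-normalised expression over the (deduplicated)
#' signature genes, averaged within each cluster. Signature genes absent
#' from the matrix or never detected are dropped and reported.
#'
#' @param normalized Log-normalised matrix.
#' @param result A [ClusterResult-class].
#' @param genes Signature gene symbols.
#' @return Named numeric score per cluster (NA for all clusters when no
#'   signature gene is detected); dropped genes in attribute
#'   \code{"dropped"}.
#' @export
meanSignatureExpression <- function(normalized, result, genes) {
    genes <- unique(genes)
    present <- intersect(genes, rownames(normalized))
    bc <- names(result@labels)
    x <- as.matrix(normalized[present, bc, drop = FALSE])
    detected <- present[rowSums(x > 0) > 0]
    cls <- sort(unique(result@labels))
    if (length(detected) == 0L) {
        out <- setNames(rep(NA_real_, length(cls)), cls)
        attr(out, "dropped") <- genes
        return(out)
    }
    x <- x[detected, , drop = FALSE]
    mu <- rowMeans(x); sg <- apply(x, 1, sd); sg[sg == 0] <- 1
    score <- colMeans((x - mu) / sg)
    out <- tapply(score, result@labels, mean)
    out <- setNames(as.numeric(out), names(out))
    attr(out, "dropped") <- setdiff(genes, detected)
    out
}

#' Map signature symbols across species
#'
#' Replaces symbols via a two-column lookup table (e.g. mouse to human
#' orthologs); one-to-many mappings are expanded, unmapped symbols are
#' dropped and counted.
#'
#' @param signature data.frame with a \code{gene} column (other columns
#'   carried along), or a character vector.
#' @param mapping data.frame, first column source symbols, second column
#'   target symbols.
#' @return Mapped signature of the same kind; number of dropped symbols
#'   in attribute \code{"nDropped"}.
#' @export
mapSpecies <- function(signature, mapping) {
    if (nrow(mapping) == 0L) stop("mapping table is empty")
    vecIn <- is.null(dim(signature))
    df <- if (vecIn) data.frame(gene = signature, stringsAsFactors = FALSE)
          else signature
    hits <- merge(df, setNames(mapping[, 1:2], c("gene", ".target")),
                  by = "gene")
    nDropped <- length(setdiff(df$gene, mapping[, 1]))
    hits$gene <- hits$.target
    hits$.target <- NULL
    hits <- hits[!duplicated(hits$gene), , drop = FALSE]
    out <- if (vecIn) hits$gene else hits
    attr(out, "nDropped") <- nDropped
    out
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term of a collection (e.g. read with [readGMT()]) for
#' over-representation of a gene set within a universe: upper-tail
#' hypergeometric p on the term restricted to the universe, BH-adjusted
#' across terms. Terms overlapping fewer than \code{minOverlapDisplay}
#' genes are flagged (the display filter); terms disjoint from the
#' universe are skipped.
#'
#' @param geneSet Character, the query genes (restricted to the universe
#'   with a warning if needed).
#' @param universe Character, the background genes.
#' @param collections Named list of character vectors.
#' @param minOverlapDisplay Overlap display filter (default 5).
#' @return data.frame: term, overlap, termSize, setSize, universeSize, p,
#'   padj, smallOverlap, genes.
#' @export
overrepresentation <- function(geneSet, universe, collections,
                               minOverlapDisplay = 5L) {
    universe <- unique(universe)
    if (!all(geneSet %in% universe)) {
        warning("gene set restricted to the universe")
        geneSet <- intersect(geneSet, universe)
    }
    geneSet <- unique(geneSet)
    N <- length(universe); nset <- length(geneSet)
    rows <- list()
    for (term in names(collections)) {
        tg <- intersect(unique(collections[[term]]), universe)
        if (length(tg) == 0L) next
        ov <- intersect(geneSet, tg)
        k <- length(ov)
        p <- phyper(k - 1L, length(tg), N - length(tg), nset,
                    lower.tail = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
            term = term, overlap = k, termSize = length(tg),
            setSize = nset, universeSize = N, p = p,
            smallOverlap = k < minOverlapDisplay,
            genes = paste(ov, collapse = ";"), stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
        return(data.frame(term = character(), overlap = integer(),
                          termSize = integer(), setSize = integer(),
                          universeSize = integer(), p = numeric(),
                          padj = numeric(), smallOverlap = logical(),
                          genes = character()))
    out <- do.call(rbind, rows)
    out$padj <- p.adjust(out$p, method = "BH")
    out[order(out$p), , drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file.
#' @return Named list of gene-symbol vectors.
#' @export
readGMT <- function(path) fgsea::gmtPathways(path)
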