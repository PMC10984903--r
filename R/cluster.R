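# Normalisation, PCA embedding, SNN-Louvain clustering, donor-specific
# flagging, per-cluster subsampling and centroid label transfer.

#' Log-normalise counts
#'
#' \code{x -> log(1 + 1e4 * x / colsum)} (natural log), keeping sparsity.
#'
#' @param counts Non-negative integer gene x nucleus matrix (sparse or
#'   dense).
#' @param scaleFactor Library scale (default 1e4).
#' @return Matrix of the same shape and class family.
#' @export
normalizeLog <- function(counts, scaleFactor = 1e4) {
    cs <- Matrix::colSums(counts)
    if (any(cs == 0)) stop("zero-sum column(s): ",
                           paste(head(which(cs == 0)), collapse = ", "))
    if (inherits(counts, "sparseMatrix")) {
        out <- counts %*% Matrix::Diagonal(x = scaleFactor / cs)
        out@x <- log1p(out@x)
        dimnames(out) <- dimnames(counts)
        out
    } else {
        log1p(sweep(counts, 2, scaleFactor / cs, `*`))
    }
}

# blockwise kNN on rows of a score matrix; returns n x k index matrix
# (self excluded)
.knnIndex <- function(pcs, k, block = 512L) {
    n <- nrow(pcs)
    k <- min(k, n - 1L)
    sq <- rowSums(pcs^2)
    idx <- matrix(0L, n, k)
    for (start in seq(1L, n, by = block)) {
        rows <- start:min(start + block - 1L, n)
        d2 <- outer(sq[rows], sq, `+`) - 2 * tcrossprod(pcs[rows, , drop = FALSE], pcs)
        for (i in seq_along(rows)) {
            d2[i, rows[i]] <- Inf
            idx[rows[i], ] <- order(d2[i, ])[seq_len(k)]
        }
    }
    idx
}

# PCA on scaled top-variable genes of a log-normalised matrix.
# Returns list(pcs, rotation, geneMeans, geneSDs, varGenes).
.pcaEmbed <- function(normalized, nPCs, nVarGenes) {
    v <- apply(normalized, 1, var)
    varGenes <- names(sort(v, decreasing = TRUE))[seq_len(min(nVarGenes, sum(v > 0)))]
    x <- as.matrix(normalized[varGenes, , drop = FALSE])
    mu <- rowMeans(x)
    sg <- apply(x, 1, sd)
    sg[sg == 0] <- 1
    xs <- t((x - mu) / sg)                       # nuclei x genes
    nPCs <- min(nPCs, ncol(xs), nrow(xs) - 1L)
    pr <- stats::prcomp(xs, center = FALSE, scale. = FALSE, rank. = nPCs)
    list(pcs = pr$x[, seq_len(nPCs), drop = FALSE],
         rotation = pr$rotation[, seq_len(nPCs), drop = FALSE],
         geneMeans = mu, geneSDs = sg, varGenes = varGenes)
}

#' SNN graph construction and Louvain clustering
#'
#' PCA on the scaled top-variable genes, k-nearest-neighbour graph in PC
#' space, shared-nearest-neighbour (Jaccard) edge weights pruned below
#' 1/15, then Louvain modularity clustering at the requested resolution.
#' The vertex order is shuffled by the seed before Louvain and labels are
#' relabelled 0-based by decreasing cluster size, so runs with the same
#' seed are identical.
#'
#' @param normalized Log-normalised gene x nucleus matrix.
#' @param params An [EmbeddingParams].
#' @param donors Optional named donor per barcode, used to fill the donor
#'   composition of the result (required for [flagDonorSpecific()]).
#' @return A [ClusterResult-class].
#' @export
clusterGraph <- function(normalized, params = EmbeddingParams(),
                         donors = NULL) {
    stopifnot(is(params, "EmbeddingParams"))
    validObject(params)
    n <- ncol(normalized)
    if (n < params@nNeighbors + 1L)
        stop("need at least nNeighbors + 1 nuclei")
    nPCs <- params@nPCs
    if (n <= nPCs) {
        warning("fewer nuclei than nPCs; reducing to ", n - 1L)
        nPCs <- n - 1L
    }
    emb <- .pcaEmbed(normalized, nPCs, params@nVarGenes)
    nn <- .knnIndex(emb$pcs, params@nNeighbors)
    k <- ncol(nn)

    # SNN: Jaccard overlap of neighbour sets (self included, Seurat-style)
    adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L),
                                j = c(as.vector(nn), seq_len(n)),
                                x = 1, dims = c(n, n))
    shared <- Matrix::tcrossprod(adj)
    shared <- methods::as(shared, "TsparseMatrix")
    keepE <- shared@i < shared@j
    i <- shared@i[keepE] + 1L; j <- shared@j[keepE] + 1L
    w <- shared@x[keepE] / (2 * (k + 1L) - shared@x[keepE])   # Jaccard
    ok <- w >= 1 / 15
    g <- igraph::graph_from_data_frame(
        data.frame(from = i[ok], to = j[ok], weight = w[ok]),
        directed = FALSE,
        vertices = data.frame(name = seq_len(n)))

    set.seed(params@seed)
    perm <- sample(n)
    gp <- igraph::permute(g, perm)
    comm <- igraph::cluster_louvain(gp, resolution = params@resolution)
    memb <- as.integer(igraph::membership(comm))[perm]
    # relabel by decreasing size, 0-based
    sizes <- table(memb)
    newLab <- setNames(seq_along(sizes) - 1L,
                       names(sort(sizes, decreasing = TRUE)))
    labels <- as.integer(newLab[as.character(memb)])
    names(labels) <- colnames(normalized)
    rownames(emb$pcs) <- colnames(normalized)

    nClust <- length(unique(labels))
    if (is.null(donors)) donors <- setNames(rep("donor0", n), colnames(normalized))
    donors <- donors[colnames(normalized)]
    comp <- table(factor(labels, levels = 0:(nClust - 1L)), donors)
    compM <- matrix(as.integer(comp), nrow = nClust,
                    dimnames = list(rownames(comp), colnames(comp)))
    new("ClusterResult", labels = labels, pcs = emb$pcs,
        rotation = emb$rotation, geneMeans = emb$geneMeans,
        geneSDs = emb$geneSDs, varGenes = emb$varGenes,
        donorComposition = compM,
        donorSpecific = rep(FALSE, nClust))
}

#' Flag donor-specific clusters
#'
#' A cluster is donor-specific when a single donor contributes strictly
#' more than 75\% of its nuclei; such clusters are excluded from the
#' association and correlation analyses downstream.
#'
#' @param result A [ClusterResult-class] with donor composition.
#' @param maxShare Dominance threshold (default 0.75, strict inequality).
#' @return The result with updated \code{donorSpecific} flags.
#' @export
flagDonorSpecific <- function(result, maxShare = 0.75) {
    comp <- result@donorComposition
    share <- apply(comp, 1, function(r) if (sum(r) == 0) 0 else max(r) / sum(r))
    result@donorSpecific <- share > maxShare
    result
}

#' Random per-cluster subsample
#'
#' Draws up to \code{n} barcodes uniformly without replacement from each
#' cluster (all of them when the cluster is smaller), for cross-region
#' integration work.
#'
#' @param result A [ClusterResult-class].
#' @param n Cap per cluster (default 1000).
#' @param seed RNG seed.
#' @return Character vector of barcodes.
#' @export
subsamplePerCluster <- function(result, n = 1000L, seed = 0L) {
    set.seed(seed)
    labs <- result@labels
    unlist(lapply(sort(unique(labs)), function(cl) {
        bc <- names(labs)[labs == cl]
        if (length(bc) <= n) bc else sample(bc, n)
    }), use.names = FALSE)
}

#' Transfer cluster labels to a new dataset
#'
#' Projects target nuclei into the source PC space (same variable genes,
#' centring and loadings) and assigns each to the label of the nearest
#' source-cluster centroid.
#'
#' @param result Source [ClusterResult-class].
#' @param targetNormalized Log-normalised gene x nucleus matrix of the
#'   target nuclei.
#' @param targetLabels Optional known target labels; when given, a
#'   source x target contingency table is attached as attribute
#'   \code{"contingency"}.
#' @return Named integer vector of mapped labels.
#' @export
transferLabels <- function(result, targetNormalized, targetLabels = NULL) {
    shared <- intersect(result@varGenes, rownames(targetNormalized))
    if (length(shared) == 0L) stop("disjoint gene sets")
    x <- as.matrix(targetNormalized[shared, , drop = FALSE])
    mu <- result@geneMeans[shared]
    sg <- result@geneSDs[shared]
    xs <- t((x - mu) / sg)
    pcs <- xs %*% result@rotation[shared, , drop = FALSE]
    cent <- centroidMatrix(result)
    d2 <- outer(rowSums(pcs^2), rowSums(cent^2), `+`) - 2 * tcrossprod(pcs, cent)
    mapped <- as.integer(rownames(cent))[max.col(-d2, ties.method = "first")]
    names(mapped) <- colnames(targetNormalized)
    if (!is.null(targetLabels))
        attr(mapped, "contingency") <- table(source = mapped,
                                             target = targetLabels[names(mapped)])
    mapped
}

#' Cluster centroids in PC space
#'
#' @param result A [ClusterResult-class].
#' @return Matrix cluster x PC, rownames are 0-based labels.
#' @export
centroidMatrix <- function(result) {
    labs <- result@labels
    cls <- sort(unique(labs))
    cent <- do.call(rbind, lapply(cls, function(cl)
        colMeans(result@pcs[labs == cl, , drop = FALSE])))
    rownames(cent) <- cls
    cent
}

#' Build a ClusterResult from known labels
#'
#' Wraps externally obtained labels (e.g. planted truth from the
#' synthetic generator, or labels imported from another tool) in a
#' [ClusterResult-class], computing the PCA embedding so the object can
#' feed the trajectory and transfer operations. Labels are relabelled
#' 0-based by decreasing cluster size.
#'
#' @param labels Named vector (barcode -> label).
#' @param normalized Log-normalised matrix covering the barcodes.
#' @param donors Optional named donor per barcode.
#' @param params An [EmbeddingParams] (only the PCA settings are used).
#' @return A [ClusterResult-class].
#' @export
clusterResultFromLabels <- function(labels, normalized, donors = NULL,
                                    params = EmbeddingParams()) {
    bc <- intersect(colnames(normalized), names(labels))
    labels <- labels[bc]
    normalized <- normalized[, bc, drop = FALSE]
    sizes <- sort(table(labels), decreasing = TRUE)
    lab <- setNames(as.integer(match(as.character(labels),
                                     names(sizes))) - 1L, bc)
    nPCs <- min(params@nPCs, length(bc) - 1L)
    emb <- .pcaEmbed(normalized, nPCs, params@nVarGenes)
    rownames(emb$pcs) <- bc
    if (is.null(donors)) donors <- setNames(rep("donor0", length(bc)), bc)
    nClust <- length(sizes)
    comp <- table(factor(lab, levels = 0:(nClust - 1L)), donors[bc])
    compM <- matrix(as.integer(comp), nrow = nClust,
                    dimnames = list(rownames(comp), colnames(comp)))
    new("ClusterResult", labels = lab, pcs = emb$pcs,
        rotation = emb$rotation, geneMeans = emb$geneMeans,
        geneSDs = emb$geneSDs, varGenes = emb$varGenes,
        donorComposition = compM, donorSpecific = rep(FALSE, nClust))
}
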