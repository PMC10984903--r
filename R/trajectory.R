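# Centroid-MST pseudotime, Moran's I on cell graphs, trajectory-gene
# selection and phasic (transitionally upregulated) gene detection.

#' Principal-tree pseudotime from homeostatic to disease clusters
#'
#' Builds a minimum spanning tree over cluster centroids in PC space,
#' projects every nucleus onto its nearest point on the tree, and defines
#' pseudotime as the geodesic (along-tree) distance from the root
#' centroid. The named trajectory comprises the nuclei whose projection
#' falls on an edge of the root-to-target tree path.
#'
#' @param result A [ClusterResult-class] (provides PCs and labels).
#' @param root,target 0-based cluster labels; must differ and be present.
#' @return A [TrajectoryResult-class].
#' @export
buildPseudotime <- function(result, root, target) {
    labs <- result@labels
    cls <- sort(unique(labs))
    if (!(root %in% cls)) stop("root cluster not present")
    if (!(target %in% cls)) stop("target cluster not present")
    if (root == target) stop("root and target must differ")
    cent <- centroidMatrix(result)
    k <- nrow(cent)
    D <- as.matrix(stats::dist(cent))
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE)
    tree <- igraph::mst(g)
    el <- igraph::as_edgelist(tree, names = FALSE)
    edgeLen <- igraph::E(tree)$weight
    rootIdx <- which(rownames(cent) == as.character(root))
    targetIdx <- which(rownames(cent) == as.character(target))
    dRoot <- as.numeric(igraph::distances(tree, v = rootIdx))
    sp <- igraph::shortest_paths(tree, from = rootIdx, to = targetIdx,
                                 output = "both")
    if (length(sp$vpath[[1]]) == 0) stop("target cluster is disconnected")
    pathV <- as.integer(rownames(cent)[as.integer(sp$vpath[[1]])])
    pathEdges <- as.integer(sp$epath[[1]])

    pcs <- result@pcs
    n <- nrow(pcs)
    bestD2 <- rep(Inf, n); bestEdge <- integer(n); bestPt <- numeric(n)
    for (e in seq_len(nrow(el))) {
        u <- cent[el[e, 1], ]; v <- cent[el[e, 2], ]
        uv <- v - u
        len2 <- sum(uv^2)
        tfrac <- if (len2 == 0) matrix(0, n, 1)
                 else pmin(1, pmax(0, (pcs %*% uv - sum(u * uv)) / len2))
        foot2 <- rowSums((pcs - rep(u, each = n) -
                          tfrac %*% t(uv))^2)
        pt <- pmin(dRoot[el[e, 1]] + tfrac * sqrt(len2),
                   dRoot[el[e, 2]] + (1 - tfrac) * sqrt(len2))
        upd <- foot2 < bestD2
        bestD2[upd] <- foot2[upd]
        bestEdge[upd] <- e
        bestPt[upd] <- pt[upd]
    }
    onPath <- bestEdge %in% pathEdges
    new("TrajectoryResult",
        edges = matrix(as.integer(rownames(cent)[as.vector(el)]),
                       ncol = 2),
        centroids = cent, root = as.integer(root),
        target = as.integer(target), path = pathV,
        pseudotime = setNames(bestPt, rownames(pcs)),
        onPath = onPath)
}

#' Symmetrised kNN adjacency in PC space
#'
#' @param pcs Nuclei x PC score matrix.
#' @param k Neighbours (default 20).
#' @return Sparse symmetric binary adjacency (dgCMatrix, zero diagonal).
#' @export
knnAdjacency <- function(pcs, k = 20L) {
    nn <- .knnIndex(pcs, k)
    n <- nrow(pcs)
    A <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nn)),
                              j = as.vector(nn), x = 1, dims = c(n, n))
    A <- ((A + Matrix::t(A)) > 0) * 1
    methods::as(A, "CsparseMatrix")
}

#' Moran's I spatial autocorrelation on a cell graph
#'
#' \eqn{I = (n/W) \sum_{ij} w_{ij}(x_i - \bar x)(x_j - \bar x) /
#' \sum_i (x_i - \bar x)^2}, with the z-score computed under the
#' normality assumption (\eqn{E[I] = -1/(n-1)}) and a one-sided upper
#' p-value.
#'
#' @param x Numeric vector (one gene's expression per nucleus), or a
#'   gene x nucleus matrix to test many genes at once.
#' @param W Weight/adjacency matrix (n x n).
#' @return For a vector: list(I, z, p). For a matrix: data.frame with one
#'   row per gene. Constant expression gives NA.
#' @export
moransI <- function(x, W) {
    single <- is.null(dim(x))
    X <- if (single) matrix(x, nrow = 1) else as.matrix(x)
    n <- ncol(X)
    stopifnot(nrow(W) == n, ncol(W) == n)
    W0 <- sum(W)
    Xc <- X - rowMeans(X)
    num <- rowSums((Xc %*% W) * Xc)
    den <- rowSums(Xc^2)
    I <- ifelse(den > 0, (n / W0) * num / den, NA_real_)
    EI <- -1 / (n - 1)
    Ws <- W + Matrix::t(W)
    S1 <- sum(Ws * Ws) / 2
    S2 <- sum((Matrix::rowSums(W) + Matrix::colSums(W))^2)
    varI <- (n^2 * S1 - n * S2 + 3 * W0^2) / (W0^2 * (n^2 - 1)) - EI^2
    z <- (I - EI) / sqrt(varI)
    p <- pnorm(z, lower.tail = FALSE)
    if (single) list(I = I[1], z = z[1], p = p[1])
    else data.frame(gene = rownames(X), I = I, z = z, p = p,
                    row.names = NULL)
}

#' Select genes variable along a trajectory
#'
#' On the trajectory's nuclei, expression is aggregated into
#' \code{nBins} equal-count pseudotime bins; genes are kept when detected
#' (bin mean > 0) in more than \code{minBins} bins, expressed in more
#' than \code{minCells} nuclei, with Moran's z above \code{zThresh} and
#' BH-adjusted Moran p below \code{alpha}. The cell graph is a
#' symmetrised kNN (k = 20) in PC space over the trajectory nuclei.
#'
#' @param traj A [TrajectoryResult-class].
#' @param normalized Log-normalised matrix.
#' @param result The [ClusterResult-class] the trajectory came from
#'   (provides the PC embedding for the graph).
#' @param nBins,minBins,minCells,zThresh,alpha Filter settings (defaults
#'   100, 50, 100, 10, 0.001).
#' @param k kNN size for the Moran graph.
#' @return data.frame per gene: nCells, binsDetected, I, z, p, padj,
#'   selected.
#' @export
selectTrajectoryGenes <- function(traj, normalized, result,
                                  nBins = 100L, minBins = 50L,
                                  minCells = 100L, zThresh = 10,
                                  alpha = 0.001, k = 20L) {
    bc <- names(traj@pseudotime)[traj@onPath]
    if (length(bc) < nBins)
        stop("trajectory has fewer than ", nBins, " nuclei")
    pt <- traj@pseudotime[bc]
    ord <- order(pt)
    bc <- bc[ord]
    X <- as.matrix(normalized[, bc, drop = FALSE])
    nCells <- rowSums(X > 0)
    bin <- ceiling(seq_along(bc) * nBins / length(bc))
    binMeans <- t(apply(X, 1, function(r) tapply(r, bin, mean)))
    binsDetected <- rowSums(binMeans > 0)
    A <- knnAdjacency(result@pcs[bc, , drop = FALSE], k)
    mi <- moransI(X, A)
    mi$padj <- p.adjust(mi$p, method = "BH")
    out <- data.frame(gene = rownames(X), nCells = nCells,
                      binsDetected = binsDetected, I = mi$I, z = mi$z,
                      p = mi$p, padj = mi$padj, row.names = NULL)
    out$selected <- out$binsDetected > minBins & out$nCells > minCells &
        !is.na(out$z) & out$z > zThresh & !is.na(out$padj) &
        out$padj < alpha
    out
}

#' Phasic (transitionally upregulated) genes along a trajectory
#'
#' Splits the trajectory's pseudotime into four rank-based quartiles of
#' equal cell counts (sizes differ by at most one nucleus). Per gene,
#' expression is z-scaled over the trajectory nuclei and averaged per
#' quartile (m1..m4); a gene is phasic when the mean over the middle two
#' quartiles exceeds both m1 and m4.
#'
#' @param traj A [TrajectoryResult-class].
#' @param normalized Log-normalised matrix.
#' @param genes Genes to evaluate (typically the selected set from
#'   [selectTrajectoryGenes()]).
#' @param strict When TRUE, require each of m2 and m3 individually to
#'   exceed m1 and m4 (default FALSE: mean rule).
#' @return data.frame: gene, m1..m4, phasic.
#' @export
phasicGenes <- function(traj, normalized, genes, strict = FALSE) {
    bc <- names(traj@pseudotime)[traj@onPath]
    pt <- traj@pseudotime[bc]
    ord <- order(pt)
    bc <- bc[ord]
    n <- length(bc)
    q <- ceiling(seq_len(n) * 4 / n)
    stopifnot(max(table(q)) - min(table(q)) <= 1)
    genes <- intersect(genes, rownames(normalized))
    X <- as.matrix(normalized[genes, bc, drop = FALSE])
    mu <- rowMeans(X); sg <- apply(X, 1, sd); sg[sg == 0] <- 1
    Z <- (X - mu) / sg
    qm <- vapply(1:4, function(j) rowMeans(Z[, q == j, drop = FALSE]),
                 numeric(length(genes)))
    qm <- matrix(qm, ncol = 4, dimnames = list(genes, paste0("m", 1:4)))
    mid <- rowMeans(Z[, q %in% 2:3, drop = FALSE])
    phasic <- if (strict)
        qm[, 2] > qm[, 1] & qm[, 2] > qm[, 4] &
        qm[, 3] > qm[, 1] & qm[, 3] > qm[, 4]
    else mid > qm[, 1] & mid > qm[, 4]
    data.frame(gene = genes, qm, mid = mid, phasic = phasic,
               row.names = NULL)
}
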