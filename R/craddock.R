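#' NCUT cost of a bipartition
#'
#' For vertex sets A and B of a weighted graph, the normalized cut is
#' CUT(A,B)/assoc(A,V) + CUT(A,B)/assoc(B,V), where CUT(A,B) is the total
#' weight of edges crossing the partition and assoc(S,V) the total weight
#' incident to S (including internal edges counted from both endpoints).
#'
#' @param weights symmetric nonnegative weight matrix (zero diagonal
#'   assumed; the diagonal is ignored)
#' @param inA logical vector: \code{TRUE} for vertices in A
#' @return the NCUT cost; \code{Inf} if either side has zero association
#' @export
ncutCost <- function(weights, inA) {
  weights <- as.matrix(weights)
  diag(weights) <- 0
  cut <- sum(weights[inA, !inA, drop = FALSE])
  degA <- sum(weights[inA, , drop = FALSE])
  degB <- sum(weights[!inA, , drop = FALSE])
  if (degA == 0 || degB == 0) return(Inf)
  cut / degA + cut / degB
}

#' Two-way normalized-cut spectral bisection
#'
#' Solves the relaxed NCUT problem via the eigenvector of the second
#' smallest eigenvalue of the normalized Laplacian, then sweeps over all
#' splits of the vertices ordered by that eigenvector and returns the
#' split minimizing [ncutCost()]. Zero-degree vertices are placed on the B
#' side.
#'
#' @param weights symmetric nonnegative weight matrix
#' @return logical membership vector (\code{TRUE} = side A)
#' @export
ncutBisect <- function(weights) {
  W <- as.matrix(weights)
  diag(W) <- 0
  n <- nrow(W)
  if (n < 2L) stop("need at least 2 vertices to bisect")
  deg <- rowSums(W)
  live <- deg > 0
  if (sum(live) < 2L) {
    # no informative structure: cut off the first vertex
    return(seq_len(n) == 1L)
  }
  Wl <- W[live, live, drop = FALSE]
  dl <- deg[live]
  ds <- 1 / sqrt(dl)
  Lsym <- diag(sum(live)) - (ds * t(ds * Wl))    # I - D^-1/2 W D^-1/2
  ev <- eigen(Lsym, symmetric = TRUE)
  x <- ds * ev$vectors[, sum(live) - 1L]          # second-smallest eigenpair
  ord <- order(x, seq_len(sum(live)))
  best <- NULL
  bestCost <- Inf
  inA <- logical(sum(live))
  # incremental sweep: move vertices into A one at a time in x-order
  cut <- 0
  volA <- 0
  volTot <- sum(dl)
  for (k in seq_len(sum(live) - 1L)) {
    v <- ord[k]
    cut <- cut + dl[v] - 2 * sum(Wl[v, inA])
    volA <- volA + dl[v]
    inA[v] <- TRUE
    volB <- volTot - volA
    if (volA == 0 || volB == 0) next
    cost <- cut / volA + cut / volB
    if (cost < bestCost - 1e-12) {
      bestCost <- cost
      best <- inA
    }
  }
  out <- logical(n)
  out[live] <- best
  out
}

#' Normalized-cut spectral clustering of the voxel graph
#'
#' Builds the 6-connectivity voxel graph with Pearson-correlation edge
#' weights, removes edges lighter than \code{edgeThreshold} (default 0.2;
#' a nonnegative threshold also removes all negative weights, and with a
#' negative configured threshold the surviving negative weights are
#' clamped to 0 since NCUT requires nonnegative weights), and then
#' repeatedly bisects the largest current cluster by normalized cut until
#' \code{targetClusters} clusters exist or nothing is left to split.
#' Connected components of the thresholded graph become clusters directly,
#' so the algorithm proceeds by cutting pieces off the largest component;
#' it can return fewer clusters than requested.
#'
#' @param volume a [VoxelVolume-class]
#' @param edgeThreshold correlation threshold in \[-1, 1\] (default 0.2)
#' @param targetClusters desired number of clusters (default 246)
#' @param window optional window restriction (\code{start}, \code{length})
#' @param windowIndex window index recorded on the result
#' @return a [Parcellation-class]; labels are assigned in decreasing
#'   cluster size
#' @export
craddockCluster <- function(volume, edgeThreshold = 0.2,
                            targetClusters = 246L, window = NULL,
                            windowIndex = 1L) {
  if (edgeThreshold < -1 || edgeThreshold > 1)
    stop("edgeThreshold must lie in [-1, 1]")
  targetClusters <- as.integer(targetClusters)
  if (targetClusters < 1L) stop("targetClusters must be at least 1")
  dim3 <- dim(volume@mask)
  maskIdx <- which(volume@mask)
  V <- length(maskIdx)
  if (V < targetClusters)
    stop("fewer masked voxels than target clusters")
  pos <- integer(prod(dim3))
  pos[maskIdx] <- seq_len(V)
  Z <- .standardize(.seriesMatrix(volume, maskIdx, window))
  .warnConstant(attr(Z, "nConstant"), "craddockCluster")

  # voxel graph edges (each undirected edge once, via +x/+y/+z neighbors)
  nbM <- .neighborMatrix(maskIdx, dim3, volume@mask)[, c(1L, 3L, 5L),
                                                     drop = FALSE]
  from <- rep(seq_len(V), 3L)
  to <- pos[as.vector(nbM)]
  ok <- !is.na(as.vector(nbM))
  from <- from[ok]; to <- to[ok]
  w <- colSums(Z[, from, drop = FALSE] * Z[, to, drop = FALSE])
  keep <- w >= edgeThreshold
  from <- from[keep]; to <- to[keep]; w <- pmax(w[keep], 0)
  if (!length(from))
    stop("no edges survive the threshold; degenerate voxel graph")

  memb <- .components(V, from, to)
  clusters <- split(seq_len(V), memb)
  # adjacency as edge list per vertex for fast submatrix construction
  while (length(clusters) < targetClusters) {
    sizes <- lengths(clusters)
    ord <- order(-sizes)
    splitId <- 0L
    for (ci in ord) {
      if (sizes[ci] < 2L) break
      sel <- clusters[[ci]]
      inSel <- from %in% sel & to %in% sel
      if (any(inSel)) { splitId <- ci; break }
    }
    if (splitId == 0L) break
    sel <- clusters[[splitId]]
    local <- match(seq_len(V), sel)
    Wsub <- matrix(0, length(sel), length(sel))
    eSel <- which(from %in% sel & to %in% sel)
    i <- local[from[eSel]]; j <- local[to[eSel]]
    Wsub[cbind(i, j)] <- w[eSel]
    Wsub[cbind(j, i)] <- w[eSel]
    side <- ncutBisect(Wsub)
    clusters[[splitId]] <- sel[side]
    clusters[[length(clusters) + 1L]] <- sel[!side]
  }

  sizes <- lengths(clusters)
  ord <- order(-sizes, vapply(clusters, min, 1L))
  labels <- array(0L, dim = dim3)
  for (i in seq_along(ord))
    labels[maskIdx[clusters[[ord[i]]]]] <- i
  Parcellation(labels, windowIndex = windowIndex, methodTag = "craddock")
}
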