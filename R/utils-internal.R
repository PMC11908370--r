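# Internal helpers: voxel indexing, 6-connectivity, standardized series.
# Voxel coordinates are 1-based (i, j, k); linear indices are R column-major.

.indexOf <- function(coords, dim3) {
  coords <- matrix(as.integer(coords), ncol = 3)
  (coords[, 3] - 1L) * (dim3[1] * dim3[2]) +
    (coords[, 2] - 1L) * dim3[1] + coords[, 1]
}

.coordsOf <- function(idx, dim3) arrayInd(idx, dim3)

.NEIGHBOR_OFFSETS <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L),
                           c(0L, 1L, 0L), c(0L, -1L, 0L),
                           c(0L, 0L, 1L), c(0L, 0L, -1L))

# Face (6-connectivity) neighbors of the given voxels, as an n x 6 integer
# matrix of linear indices; NA where the neighbor falls outside the grid or
# (when mask given) outside the mask.
.neighborMatrix <- function(idx, dim3, mask = NULL) {
  co <- .coordsOf(idx, dim3)
  out <- matrix(NA_integer_, nrow = length(idx), ncol = 6L)
  for (k in seq_len(6L)) {
    sc <- sweep(co, 2L, .NEIGHBOR_OFFSETS[k, ], "+")
    ok <- sc[, 1] >= 1L & sc[, 1] <= dim3[1] &
          sc[, 2] >= 1L & sc[, 2] <= dim3[2] &
          sc[, 3] >= 1L & sc[, 3] <= dim3[3]
    if (any(ok)) {
      lin <- .indexOf(sc[ok, , drop = FALSE], dim3)
      if (!is.null(mask)) {
        keep <- mask[lin]
        lin[!keep] <- NA_integer_
      }
      out[ok, k] <- lin
    }
  }
  out
}

# Flat (voxels x time) view of the 4D data
.flatData <- function(volume) {
  d <- dim(volume@data)
  flat <- volume@data
  dim(flat) <- c(prod(d[1:3]), d[4])
  flat
}

# Time x voxel series matrix for the given linear indices, optionally
# restricted to a window (start, length), start 1-based.
.seriesMatrix <- function(volume, voxels, window = NULL) {
  flat <- .flatData(volume)
  m <- t(flat[voxels, , drop = FALSE])
  if (!is.null(window)) {
    start <- as.integer(window[["start"]])
    len <- as.integer(window[["length"]])
    m <- m[start:(start + len - 1L), , drop = FALSE]
  }
  m
}

# Center and scale columns to unit Euclidean norm so that crossprod(Z)
# yields Pearson correlations. Constant columns become all-zero and the
# count of such columns is attached as attribute "nConstant" (their
# correlations are then 0 by the package-wide zero-variance policy).
.standardize <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X), "-")
  nrm <- sqrt(colSums(Xc^2))
  const <- nrm < .Machine$double.eps^0.5
  nrm[const] <- 1
  Z <- sweep(Xc, 2L, nrm, "/")
  if (any(const)) Z[, const] <- 0
  attr(Z, "nConstant") <- sum(const)
  Z
}

.warnConstant <- function(n, context) {
  if (n > 0L)
    warning(sprintf("%d constant time series in %s; their correlations are set to 0",
                    n, context), call. = FALSE)
}

# Connected components over an undirected edge list on n vertices
# (union-find with path halving). Returns an integer membership vector.
.components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    a <- find(from[e]); b <- find(to[e])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, sort(unique(roots)))
}

# Check that a voxel set is 6-connected within the grid (flood fill).
.isConnected <- function(voxels, dim3) {
  if (length(voxels) <= 1L) return(TRUE)
  inSet <- logical(prod(dim3))
  inSet[voxels] <- TRUE
  seen <- logical(prod(dim3))
  queue <- voxels[1L]
  seen[queue] <- TRUE
  count <- 1L
  while (length(queue)) {
    nb <- .neighborMatrix(queue, dim3)
    nb <- nb[!is.na(nb)]
    nb <- unique(nb[inSet[nb] & !seen[nb]])
    seen[nb] <- TRUE
    count <- count + length(nb)
    queue <- nb
  }
  count == length(voxels)
}
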