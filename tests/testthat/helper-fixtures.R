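# Shared fixtures and independent oracles. Oracles deliberately use naive
# formulations (double loops, enumeration) so they cannot share a code path
# with the implementation they check.

# VoxelVolume whose voxel v carries series[, v]; full mask by default.
volumeFromSeries <- function(series, dim3, mask = NULL) {
  stopifnot(ncol(series) == prod(dim3))
  data <- array(0, dim = c(dim3, nrow(series)))
  flat <- t(series)                      # voxels x time
  dim(flat) <- c(prod(dim3), nrow(series))
  data[] <- flat
  if (is.null(mask)) mask <- array(TRUE, dim = dim3)
  VoxelVolume(data, mask = mask)
}

# T x k matrix of zero-mean series whose sample correlation matrix is
# exactly C (orthonormal basis orthogonal to the intercept, times chol(C)).
seriesWithCorrelation <- function(C, nT, seed = 1) {
  set.seed(seed)
  k <- ncol(C)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(nT * k), nT))))[, -1, drop = FALSE]
  Q %*% chol(C)
}

jaccardOracle <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# mean pairwise Pearson correlation by explicit double loop over cor()
bruteMeanPairCorrelation <- function(series) {
  k <- ncol(series)
  vals <- c()
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    vals <- c(vals, cor(series[, i], series[, j]))
  mean(vals)
}

# Kendall's W by direct rank-sum evaluation (midranks, uncorrected)
bruteKendallW <- function(series) {
  n <- nrow(series)
  K <- ncol(series)
  R <- rowSums(apply(series, 2, rank))
  12 * sum((R - mean(R))^2) / (K^2 * (n^3 - n))
}

# minimum NCUT cost over all bipartitions by exhaustive enumeration
bruteNcutMin <- function(W) {
  n <- nrow(W)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    inA <- c(as.logical(bitwAnd(code, 2^(0:(n - 2)))), FALSE)
    best <- min(best, mlbrainnet::ncutCost(W, inA))
  }
  best
}

# is a voxel set 6-connected? breadth-first flood fill over coordinates
floodFillConnected <- function(voxels, dim3) {
  if (length(voxels) <= 1) return(TRUE)
  co <- arrayInd(voxels, dim3)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  inSet <- key(co)
  seen <- inSet[1]
  frontier <- co[1, , drop = FALSE]
  offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  while (nrow(frontier)) {
    nxt <- NULL
    for (r in seq_len(nrow(frontier))) for (k in 1:6) {
      cand <- frontier[r, ] + offs[k, ]
      ck <- paste(cand[1], cand[2], cand[3])
      if (ck %in% inSet && !(ck %in% seen)) {
        seen <- c(seen, ck)
        nxt <- rbind(nxt, cand)
      }
    }
    frontier <- if (is.null(nxt)) matrix(numeric(0), 0, 3) else nxt
  }
  length(seen) == length(inSet)
}

# weighted two-community random graph on which spectral NCUT should find
# the planted optimum
twoBlockGraph <- function(n1, n2, seed) {
  set.seed(seed)
  n <- n1 + n2
  W <- matrix(runif(n * n, 0, 0.1), n)
  W[seq_len(n1), seq_len(n1)] <- runif(n1 * n1, 0.8, 1)
  W[(n1 + 1):n, (n1 + 1):n] <- runif(n2 * n2, 0.8, 1)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# Two-layer network in which ROI 1 (10 voxels on layer 1) turns into a
# successor keeping `kept` of its voxels plus `gained` voxels taken from
# the other ROI; the grid is a 30x1x1 line and ROI 2 absorbs the rest.
reorganizedNetwork <- function(kept, gained) {
  dim3 <- c(30, 1, 1)
  lb1 <- array(0L, dim3)
  lb1[1:10] <- 1L
  lb1[11:30] <- 2L
  lb2 <- array(0L, dim3)
  succ <- c(seq_len(kept), if (gained > 0) 10L + seq_len(gained))
  lb2[succ] <- 1L
  lb2[setdiff(1:30, succ)] <- 2L
  set.seed(99)
  vol <- VoxelVolume(array(rnorm(30 * 20), c(dim3, 20)))
  buildNetwork(vol, list(Parcellation(lb1), Parcellation(lb2)), 10)
}

# planted two-block volume: two 6-connected blocks of internally identical,
# mutually independent series on a 4x2x1 grid
twoBlockVolume <- function(nT = 40, seed = 5) {
  set.seed(seed)
  s1 <- rnorm(nT); s2 <- rnorm(nT)
  series <- cbind(s1, s1, s2, s2, s1, s1, s2, s2)
  # grid 4x2x1, column-major: voxels 1..4 = x 1..4 at y=1; 5..8 at y=2
  volumeFromSeries(series, c(4, 2, 1))
}
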