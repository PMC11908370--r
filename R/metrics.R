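#' Spatial consistency (functional homogeneity) of an ROI
#'
#' The mean Pearson correlation over all distinct pairs of voxel time
#' series in the ROI. This is the functional-homogeneity objective that the
#' greedy parcellation optimizes. Values lie in \[-1, 1\]; an ROI whose
#' voxels carry identical signals has consistency 1.
#'
#' Constant (zero-variance) series contribute correlation 0 with a warning,
#' avoiding NaN propagation.
#'
#' @param volume a [VoxelVolume-class]
#' @param voxels integer vector of linear voxel indices (all masked),
#'   length >= 2
#' @param window optional list/row with elements \code{start} and
#'   \code{length} restricting the time axis
#' @return mean pairwise correlation, a single number in \[-1, 1\]
#' @examples
#' vol <- VoxelVolume(array(rnorm(8 * 20), c(2, 2, 2, 20)))
#' spatialConsistency(vol, maskIndices(vol)[1:4])
#' @export
spatialConsistency <- function(volume, voxels, window = NULL) {
  voxels <- as.integer(voxels)
  if (length(voxels) < 2L)
    stop("spatial consistency is undefined for fewer than 2 voxels")
  if (!all(volume@mask[voxels]))
    stop("all voxels must lie inside the mask")
  Z <- .standardize(.seriesMatrix(volume, voxels, window))
  .warnConstant(attr(Z, "nConstant"), "spatialConsistency")
  .meanPairCorrelation(Z)
}

# Mean off-diagonal entry of crossprod(Z) without forming it when large.
.meanPairCorrelation <- function(Z) {
  k <- ncol(Z)
  # sum of all pairwise correlations = (|colsum vector|^2 - k') / 2 where
  # k' = number of non-constant columns (unit diagonal) -- constant columns
  # have zero norm, so subtract only their actual diagonal (0).
  diagSum <- sum(colSums(Z^2))
  s <- rowSums(Z)
  tot <- (sum(s^2) - diagSum) / 2
  tot / (k * (k - 1) / 2)
}

#' Regional homogeneity (ReHo) of a voxel
#'
#' Kendall's coefficient of concordance W over the voxel's time series and
#' those of its face-sharing masked neighbors. With a complete
#' 6-neighborhood, K = 7 series enter the computation; at mask boundaries K
#' shrinks to the available neighbors plus the center. Ranks are midranks;
#' no tie-correction term is applied. W is in \[0, 1\], reaching 1 when all
#' series are rank-identical without ties.
#'
#' @param volume a [VoxelVolume-class]
#' @param voxel a single linear voxel index, or a length-3 (i, j, k)
#'   coordinate vector (1-based)
#' @param window optional window restriction (\code{start}, \code{length})
#' @return Kendall's W in \[0, 1\]
#' @examples
#' vol <- VoxelVolume(array(rnorm(27 * 30), c(3, 3, 3, 30)))
#' regionalHomogeneity(vol, c(2, 2, 2))
#' @export
regionalHomogeneity <- function(volume, voxel, window = NULL) {
  dim3 <- dim(volume@mask)
  if (length(voxel) == 3L) voxel <- .indexOf(matrix(voxel, ncol = 3), dim3)
  voxel <- as.integer(voxel)
  if (length(voxel) != 1L) stop("voxel must be a single index or coordinate")
  if (!volume@mask[voxel]) stop("voxel must lie inside the mask")
  nb <- .neighborMatrix(voxel, dim3, volume@mask)
  nbh <- c(voxel, nb[!is.na(nb)])
  X <- .seriesMatrix(volume, nbh, window)
  .kendallW(X)
}

# Kendall's W over the columns of X (time x series), midranks, uncorrected.
.kendallW <- function(X) {
  n <- nrow(X)
  K <- ncol(X)
  ranks <- apply(X, 2L, rank)
  Ri <- rowSums(ranks)
  12 * sum((Ri - mean(Ri))^2) / (K^2 * (n^3 - n))
}

#' Within- and between-ROI correlation distributions
#'
#' Pools Pearson correlations of voxel pairs that share an ROI (within) and
#' pairs assigned to different ROIs (between), after discarding
#' single-voxel ROIs. When the number of between-ROI pairs exceeds
#' \code{maxPairs} they are uniformly subsampled. Also reports the per-ROI
#' spatial consistency and the excess-area statistic separating the two
#' distributions.
#'
#' @param volume a [VoxelVolume-class]
#' @param parcellation a [Parcellation-class]
#' @param maxPairs cap on the number of between-ROI pairs (default 10000)
#' @param seed optional RNG seed for the subsampling
#' @param binWidth histogram bin width for the excess area (default 0.01)
#' @param window optional window restriction
#' @return list with elements \code{perRoiConsistency} (named numeric),
#'   \code{within}, \code{between} (numeric vectors of correlations) and
#'   \code{excessArea}
#' @export
correlationDistributions <- function(volume, parcellation, maxPairs = 10000L,
                                     seed = NULL, binWidth = 0.01,
                                     window = NULL) {
  keep <- excludeSingleVoxelRois(parcellation)$parcellation
  labels <- roiLabels(keep)
  if (!length(labels))
    stop("parcellation has no multi-voxel ROIs")
  if (!is.null(seed)) set.seed(seed)
  voxels <- which(keep@labels > 0L)
  lab <- keep@labels[voxels]
  Z <- .standardize(.seriesMatrix(volume, voxels, window))
  .warnConstant(attr(Z, "nConstant"), "correlationDistributions")

  within <- numeric(0)
  perRoi <- numeric(length(labels))
  names(perRoi) <- labels
  for (l in labels) {
    cols <- which(lab == l)
    C <- crossprod(Z[, cols, drop = FALSE])
    vals <- C[upper.tri(C)]
    within <- c(within, vals)
    perRoi[as.character(l)] <- mean(vals)
  }

  V <- length(voxels)
  nWithin <- length(within)
  nTotal <- V * (V - 1) / 2
  nBetween <- nTotal - nWithin
  if (nBetween <= maxPairs) {
    C <- crossprod(Z)
    diff <- outer(lab, lab, "!=")
    between <- C[upper.tri(C) & diff]
  } else {
    # rejection-sample unordered pairs from different ROIs
    between <- numeric(0)
    while (length(between) < maxPairs) {
      need <- maxPairs - length(between)
      a <- sample.int(V, 2L * need, replace = TRUE)
      b <- sample.int(V, 2L * need, replace = TRUE)
      ok <- a != b & lab[a] != lab[b]
      a <- a[ok]; b <- b[ok]
      if (!length(a)) next
      take <- seq_len(min(need, length(a)))
      between <- c(between, colSums(Z[, a[take], drop = FALSE] *
                                    Z[, b[take], drop = FALSE]))
    }
  }
  if (!length(between)) {
    ea <- NA_real_
  } else {
    ea <- excessArea(within, between, binWidth)
  }
  list(perRoiConsistency = perRoi, within = within, between = between,
       excessArea = ea)
}

#' Excess area between within- and between-ROI correlation densities
#'
#' Both samples are histogrammed on a shared grid over \[-1, 1\] with
#' density normalization; the statistic is the integrated positive part of
#' (within density - between density). It is 0 when the distributions
#' coincide and approaches 1 when their supports are disjoint; larger
#' values mean within-ROI correlations dominate the high end.
#'
#' @param within numeric vector of within-ROI correlations
#' @param between numeric vector of between-ROI correlations
#' @param binWidth histogram bin width over \[-1, 1\] (default 0.01)
#' @return nonnegative excess area
#' @examples
#' excessArea(rep(1, 10), rep(-1, 10))  # disjoint supports: 1
#' @export
excessArea <- function(within, between, binWidth = 0.01) {
  if (!length(within) || !length(between))
    stop("both correlation samples must be non-empty")
  if (binWidth <= 0) stop("binWidth must be positive")
  # guard against correlations leaking past +/-1 by floating-point error
  within <- pmin(pmax(within, -1), 1)
  between <- pmin(pmax(between, -1), 1)
  breaks <- seq(-1, 1, by = binWidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  hw <- graphics::hist(within, breaks = breaks, plot = FALSE)
  hb <- graphics::hist(between, breaks = breaks, plot = FALSE)
  widths <- diff(breaks)
  sum(pmax(0, hw$density - hb$density) * widths)
}
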