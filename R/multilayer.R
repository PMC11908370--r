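#' Split a recording into non-overlapping time windows
#'
#' Consecutive half-open windows of \code{windowLength} samples starting
#' at sample 1; trailing samples that do not fill a whole window are
#' discarded. The default of 80 samples corresponds to 8 s at a 100 ms
#' sampling interval and gives stable spatial-consistency estimates.
#'
#' @param volume a [VoxelVolume-class]
#' @param windowLength samples per window (default 80, minimum 2)
#' @return data.frame with columns \code{start} (1-based) and
#'   \code{length}, one row per window
#' @examples
#' vol <- VoxelVolume(array(rnorm(8 * 250), c(2, 2, 2, 250)))
#' splitWindows(vol, 80)   # 3 windows, 10 samples dropped
#' @export
splitWindows <- function(volume, windowLength = 80L) {
  windowLength <- as.integer(windowLength)
  if (windowLength < 2L) stop("windowLength must be at least 2")
  nT <- nTimepoints(volume)
  if (nT < windowLength)
    stop(sprintf("volume has %d time points, fewer than one %d-sample window",
                 nT, windowLength))
  n <- nT %/% windowLength
  data.frame(start = (seq_len(n) - 1L) * windowLength + 1L,
             length = windowLength)
}

#' Mean time series of an ROI
#'
#' Element-wise arithmetic mean over the ROI's voxel series, restricted to
#' one time window.
#'
#' @param volume a [VoxelVolume-class]
#' @param roiVoxels non-empty integer vector of masked voxel indices
#' @param window list/row with \code{start} and \code{length};
#'   \code{NULL} uses the full time axis
#' @return numeric vector of length equal to the window length
#' @export
roiMeanTimeseries <- function(volume, roiVoxels, window = NULL) {
  if (!length(roiVoxels)) stop("ROI voxel set must be non-empty")
  if (!all(volume@mask[roiVoxels]))
    stop("all ROI voxels must lie inside the mask")
  rowMeans(.seriesMatrix(volume, roiVoxels, window))
}

#' Intralayer correlation edges between ROI mean series
#'
#' Pearson correlations between all pairs of ROI time series within one
#' window; the intralayer graph is complete. Constant series yield weight
#' 0 with a warning.
#'
#' @param roiSeries matrix (time x ROI) of mean series, columns named by
#'   ROI label, or a named list of equal-length series
#' @return symmetric correlation matrix; the diagonal is set to \code{NA}
#'   since self-edges are not part of the graph
#' @export
intralayerEdges <- function(roiSeries) {
  if (is.list(roiSeries)) roiSeries <- do.call(cbind, roiSeries)
  if (ncol(roiSeries) < 2L) stop("at least 2 ROIs required")
  Z <- .standardize(roiSeries)
  .warnConstant(attr(Z, "nConstant"), "intralayerEdges")
  C <- crossprod(Z)
  diag(C) <- NA_real_
  C
}

#' Interlayer Jaccard edges between two parcellations
#'
#' For every pair of ROIs on consecutive layers whose voxel sets overlap,
#' the edge weight is the Jaccard index |intersection| / |union|. Pairs
#' with empty intersection produce no edge. Identical voxel sets give
#' weight 1.
#'
#' @param parcT a [Parcellation-class] for layer t
#' @param parcT1 a [Parcellation-class] for layer t+1, same voxel grid
#' @return data.frame with columns \code{from} (label on t), \code{to}
#'   (label on t+1), \code{weight} in (0, 1]
#' @export
interlayerEdges <- function(parcT, parcT1) {
  if (!identical(dim(parcT@labels), dim(parcT1@labels)))
    stop("parcellations must share the same voxel grid")
  a <- as.vector(parcT@labels)
  b <- as.vector(parcT1@labels)
  both <- a > 0L & b > 0L
  sizesA <- roiSizes(parcT)
  sizesB <- roiSizes(parcT1)
  if (!any(both))
    return(data.frame(from = integer(0), to = integer(0),
                      weight = numeric(0)))
  inter <- table(a[both], b[both])
  df <- as.data.frame(inter, stringsAsFactors = FALSE)
  names(df) <- c("from", "to", "weight")
  df <- df[df$weight > 0, ]
  from <- as.integer(df$from)
  to <- as.integer(df$to)
  i <- as.numeric(df$weight)
  u <- as.numeric(sizesA[as.character(from)]) +
    as.numeric(sizesB[as.character(to)]) - i
  out <- data.frame(from = from, to = to, weight = i / u)
  out <- out[order(out$from, out$to), ]
  rownames(out) <- NULL
  out
}

#' Assemble the node-reconfiguring multilayer network
#'
#' Splits the volume into windows (layers), takes the given per-window
#' parcellation's ROIs as that layer's nodes, computes ROI mean series and
#' the complete intralayer Pearson-correlation graph per layer, and
#' connects consecutive layers with Jaccard-overlap interlayer edges.
#' Single-voxel ROIs are expected to be excluded beforehand
#' ([excludeSingleVoxelRois()]). With the same (static) parcellation on
#' every layer the result is multiplex: each node has exactly one
#' interlayer edge, of weight 1, to its own successor.
#'
#' @param volume a [VoxelVolume-class]
#' @param parcellations list of [Parcellation-class], one per window
#' @param windowLength samples per window (default 80)
#' @return a [MultilayerNetwork-class]
#' @export
buildNetwork <- function(volume, parcellations, windowLength = 80L) {
  windows <- splitWindows(volume, windowLength)
  if (length(parcellations) != nrow(windows))
    stop(sprintf("%d parcellations supplied for %d windows",
                 length(parcellations), nrow(windows)))
  nl <- nrow(windows)
  nodes <- vector("list", nl)
  series <- vector("list", nl)
  intra <- vector("list", nl)
  for (t in seq_len(nl)) {
    p <- parcellations[[t]]
    labs <- roiLabels(p)
    nodes[[t]] <- lapply(stats::setNames(labs, labs),
                         function(l) roiVoxels(p, l))
    M <- vapply(nodes[[t]], function(vox)
      roiMeanTimeseries(volume, vox, windows[t, ]),
      numeric(windows$length[t]))
    if (is.null(dim(M))) M <- matrix(M, ncol = length(labs))
    colnames(M) <- as.character(labs)
    series[[t]] <- M
    intra[[t]] <- if (length(labs) >= 2L) intralayerEdges(M) else
      matrix(NA_real_, length(labs), length(labs),
             dimnames = list(labs, labs))
  }
  inter <- vector("list", max(nl - 1L, 0L))
  if (nl > 1L)
    for (t in seq_len(nl - 1L))
      inter[[t]] <- interlayerEdges(parcellations[[t]],
                                    parcellations[[t + 1L]])
  new("MultilayerNetwork", windows = windows, nodes = nodes,
      series = series, intralayer = intra, interlayer = inter,
      gridDim = dim(volume@mask))
}
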