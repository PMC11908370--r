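#' Stability score of an ROI node
#'
#' The weight of the heaviest interlayer edge from the node to any ROI on
#' the next layer, i.e. the node's best Jaccard overlap one window ahead.
#' 1 means an identical ROI exists on the next layer; 0 means the ROI
#' disperses completely (no interlayer edge). Undefined for nodes on the
#' last layer.
#'
#' @param network a [MultilayerNetwork-class]
#' @param layer layer index of the node (must not be the last layer)
#' @param label ROI label of the node
#' @return stability score in \[0, 1\]
#' @export
stabilityScore <- function(network, layer, label) {
  layer <- .checkLayer(network, layer)
  if (layer >= nLayers(network))
    stop("stability score is undefined for nodes on the last layer")
  label <- as.integer(label)
  if (!as.character(label) %in% names(network@nodes[[layer]]))
    stop(sprintf("no ROI %d on layer %d", label, layer))
  e <- network@interlayer[[layer]]
  w <- e$weight[e$from == label]
  if (!length(w)) 0 else max(w)
}

#' Stability scores of all eligible nodes
#'
#' Pools the stability score of every node on every layer except the last
#' (where the score is undefined).
#'
#' @param network a [MultilayerNetwork-class]
#' @return data.frame with columns \code{layer}, \code{label},
#'   \code{stability}
#' @export
stabilityScores <- function(network) {
  nl <- nLayers(network)
  out <- list()
  for (t in seq_len(max(nl - 1L, 0L))) {
    labs <- as.integer(names(network@nodes[[t]]))
    out[[t]] <- data.frame(
      layer = t, label = labs,
      stability = vapply(labs, function(l)
        stabilityScore(network, t, l), numeric(1)))
  }
  do.call(rbind, out)
}

#' Trajectory of an ROI across later layers
#'
#' For the reference node's voxel set, the best Jaccard overlap against
#' all ROIs on each temporally subsequent layer. A value of 1 at offset k
#' means the ROI exists unchanged k windows later; 0 means its voxels have
#' fully dispersed. Computed from the voxel sets directly, not by chaining
#' interlayer edges, so an ROI that shatters and later reassembles shows a
#' dip followed by a return towards 1.
#'
#' @param network a [MultilayerNetwork-class]
#' @param layer layer of the reference node
#' @param label ROI label of the reference node
#' @param minSize minimum reference ROI size in voxels (default 5);
#'   smaller ROIs give noisy overlap values
#' @return data.frame with columns \code{offset}, \code{layer} (the target
#'   layer), \code{value}; zero rows when the reference sits on the last
#'   layer
#' @export
trajectory <- function(network, layer, label, minSize = 5L) {
  layer <- .checkLayer(network, layer)
  label <- as.integer(label)
  ref <- network@nodes[[layer]][[as.character(label)]]
  if (is.null(ref))
    stop(sprintf("no ROI %d on layer %d", label, layer))
  if (length(ref) < minSize)
    stop(sprintf("reference ROI has %d voxels, below minSize = %d",
                 length(ref), minSize))
  nl <- nLayers(network)
  if (layer >= nl)
    return(data.frame(offset = integer(0), layer = integer(0),
                      value = numeric(0)))
  targets <- (layer + 1L):nl
  vals <- vapply(targets, function(t) {
    sets <- network@nodes[[t]]
    if (!length(sets)) return(0)
    max(vapply(sets, function(s) {
      i <- length(intersect(ref, s))
      if (i == 0L) 0 else i / (length(ref) + length(s) - i)
    }, numeric(1)))
  }, numeric(1))
  data.frame(offset = targets - layer, layer = targets, value = vals)
}

#' Pairwise stability score of two same-layer nodes
#'
#' The arithmetic mean of the two nodes' stability scores; used to relate
#' the intralayer edge weight of an ROI pair to how stable the pair is
#' across the following window.
#'
#' @param network a [MultilayerNetwork-class]
#' @param layer common layer of both nodes (not the last layer)
#' @param labelA,labelB ROI labels
#' @return mean of the two stability scores
#' @export
pairwiseStability <- function(network, layer, labelA, labelB) {
  (stabilityScore(network, layer, labelA) +
     stabilityScore(network, layer, labelB)) / 2
}

#' Mean intralayer correlation of a node
#'
#' The mean weight of the node's intralayer edges to all other ROIs on its
#' layer; a measure of how strongly the ROI couples to the rest of the
#' network within its time window.
#'
#' @param network a [MultilayerNetwork-class]
#' @param layer layer index
#' @param label ROI label
#' @return mean correlation in \[-1, 1\]
#' @export
meanIntralayerCorrelation <- function(network, layer, label) {
  layer <- .checkLayer(network, layer)
  C <- network@intralayer[[layer]]
  if (nrow(C) < 2L)
    stop("mean intralayer correlation is undefined on a singleton layer")
  key <- as.character(as.integer(label))
  if (!key %in% rownames(C))
    stop(sprintf("no ROI %s on layer %d", key, layer))
  mean(C[key, colnames(C) != key])
}

#' Bin a quantity by another on \[0, 1\]
#'
#' Means of \code{y} within bins of \code{x}, using a closed first bin
#' \[0, w\] and half-open subsequent bins (w, 2w\], ...; x = 0.1 falls in
#' the first bin of width 0.1 and x = 0.1001 in the second. Pool values
#' across layers and runs before calling.
#'
#' @param x numeric values in \[0, 1\] (e.g. stability scores)
#' @param y numeric values paired with \code{x}
#' @param binWidth bin width (default 0.1)
#' @return data.frame with columns \code{binLow}, \code{binHigh},
#'   \code{mean}, \code{count}; one row per bin covering \[0, 1\]
#' @export
binnedCurve <- function(x, y, binWidth = 0.1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (binWidth <= 0 || binWidth > 1) stop("binWidth must lie in (0, 1]")
  if (any(x < 0 | x > 1)) stop("x values must lie in [0, 1]")
  nBins <- ceiling(1 / binWidth - 1e-9)
  # tolerance keeps exact multiples of the width in their closed-top bin
  idx <- ceiling(x / binWidth - 1e-9)
  idx[idx < 1L] <- 1L
  means <- rep(NA_real_, nBins)
  counts <- integer(nBins)
  agg <- tapply(y, factor(idx, levels = seq_len(nBins)), mean)
  means[] <- as.numeric(agg)
  counts[] <- as.integer(table(factor(idx, levels = seq_len(nBins))))
  data.frame(binLow = (seq_len(nBins) - 1) * binWidth,
             binHigh = pmin(seq_len(nBins) * binWidth, 1),
             mean = means, count = counts)
}

#' Empirical CDF of interlayer weights or stability scores
#'
#' Pools the requested quantity over all layers and returns its empirical
#' cumulative distribution. On a static (multiplex) input all interlayer
#' weights equal 1 and the CDF is a single step at 1.
#'
#' @param network a [MultilayerNetwork-class]
#' @param what \code{"weights"} for interlayer edge weights,
#'   \code{"stability"} for node stability scores
#' @return data.frame with columns \code{value} (sorted) and \code{cdf}
#' @export
interlayerWeightCdf <- function(network, what = c("weights", "stability")) {
  what <- match.arg(what)
  vals <- if (what == "weights") {
    unlist(lapply(network@interlayer, function(e) e$weight))
  } else {
    stabilityScores(network)$stability
  }
  if (!length(vals))
    return(data.frame(value = numeric(0), cdf = numeric(0)))
  vals <- sort(vals)
  data.frame(value = vals, cdf = seq_along(vals) / length(vals))
}

#' Consistency carryover from window t to window t+1
#'
#' Applies the ROI boundaries obtained in window t to the data of both
#' window t and window t+1 and compares per-ROI spatial consistency.
#' Negative mean change indicates that ROIs were more consistent in the
#' window they were optimized for, the signature of genuinely
#' reconfiguring functional units; for parcellations defined without
#' regard to the data (static or random) the expected change is zero.
#' Single-voxel ROIs are excluded.
#'
#' @param volume a [VoxelVolume-class]
#' @param parcT the [Parcellation-class] defined in window t
#' @param windowT,windowT1 lists/rows with \code{start} and \code{length};
#'   must not overlap
#' @return list with \code{perRoi} (data.frame \code{label}, \code{phiT},
#'   \code{phiT1}, \code{change}), \code{meanChange} (mean of
#'   phiT1 - phiT), \code{sdChange}, and \code{relativeChange}
#'   (meanChange divided by mean phiT)
#' @export
consistencyCarryover <- function(volume, parcT, windowT, windowT1) {
  s0 <- as.integer(windowT[["start"]]); l0 <- as.integer(windowT[["length"]])
  s1 <- as.integer(windowT1[["start"]]); l1 <- as.integer(windowT1[["length"]])
  if (max(s0, s1) < min(s0 + l0, s1 + l1))
    stop("windows must not overlap")
  p <- excludeSingleVoxelRois(parcT)$parcellation
  labs <- roiLabels(p)
  if (!length(labs)) stop("no multi-voxel ROIs in the parcellation")
  phiT <- vapply(labs, function(l)
    spatialConsistency(volume, roiVoxels(p, l), windowT), numeric(1))
  phiT1 <- vapply(labs, function(l)
    spatialConsistency(volume, roiVoxels(p, l), windowT1), numeric(1))
  change <- phiT1 - phiT
  list(perRoi = data.frame(label = labs, phiT = phiT, phiT1 = phiT1,
                           change = change),
       meanChange = mean(change),
       sdChange = stats::sd(change),
       relativeChange = mean(change) / mean(phiT))
}
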