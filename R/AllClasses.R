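#' @import methods
NULL

#' VoxelVolume: a masked 4D voxel time-series volume
#'
#' Container for voxel-level BOLD-like data: a 4D array (three spatial axes
#' and time) together with a logical brain mask and the sampling interval.
#' All computations in the package operate on the voxels inside the mask.
#'
#' @slot data numeric 4D array, dimensions (x, y, z, t).
#' @slot mask logical 3D array matching the spatial dimensions of
#'   \code{data}; \code{TRUE} marks voxels that take part in analysis.
#' @slot sampleInterval seconds per time point (default 0.1, i.e. a
#'   100 ms repetition time).
#' @slot affine 4x4 voxel-to-world matrix, retained for NIfTI write-back.
#'
#' @seealso [VoxelVolume()], [readVolume()], [generateVoxelTimeseries()]
#' @exportClass VoxelVolume
setClass("VoxelVolume",
         slots = c(data = "array",
                   mask = "array",
                   sampleInterval = "numeric",
                   affine = "matrix"))

setValidity("VoxelVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4D array (x, y, z, t)")
  if (d[4] < 2L)
    return("data must have at least 2 time points")
  if (!is.logical(object@mask))
    return("mask must be a logical array")
  if (!identical(dim(object@mask), d[1:3]))
    return(sprintf("mask shape (%s) does not match spatial shape of data (%s)",
                   paste(dim(object@mask), collapse = "x"),
                   paste(d[1:3], collapse = "x")))
  if (length(object@sampleInterval) != 1L || object@sampleInterval <= 0)
    return("sampleInterval must be a single positive number")
  if (!identical(dim(object@affine), c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  idx <- which(object@mask)
  if (length(idx)) {
    flat <- object@data
    dim(flat) <- c(prod(d[1:3]), d[4])
    if (!all(is.finite(flat[idx, ])))
      return("masked voxel time series must be finite")
  }
  TRUE
})

#' Construct a VoxelVolume
#'
#' @param data numeric 4D array (x, y, z, t).
#' @param mask logical 3D array; if \code{NULL}, a mask is derived by
#'   keeping voxels whose series are finite with nonzero variance.
#' @param sampleInterval seconds per sample (default 0.1).
#' @param affine optional 4x4 voxel-to-world matrix (default identity).
#' @return A [VoxelVolume-class] object.
#' @examples
#' vol <- VoxelVolume(array(rnorm(2 * 2 * 2 * 10), c(2, 2, 2, 10)))
#' nTimepoints(vol)
#' @export
VoxelVolume <- function(data, mask = NULL, sampleInterval = 0.1,
                        affine = diag(4)) {
  storage.mode(data) <- "double"
  if (is.null(mask)) {
    d <- dim(data)
    flat <- data
    dim(flat) <- c(prod(d[1:3]), d[4])
    v <- apply(flat, 1L, stats::var)
    mask <- array(is.finite(v) & v > 0, dim = d[1:3])
  }
  if (!is.logical(mask)) mask <- array(mask != 0, dim = dim(mask))
  new("VoxelVolume", data = data, mask = mask,
      sampleInterval = sampleInterval, affine = affine)
}

#' Parcellation: assignment of masked voxels to ROI labels
#'
#' An integer label volume on the voxel grid: 0 marks unassigned voxels,
#' positive integers mark ROI membership for one time window. For
#' region-grown parcellations the seed voxel of each ROI is retained, which
#' the synthetic-data generator requires.
#'
#' @slot labels integer 3D array; 0 = unassigned.
#' @slot windowIndex index of the time window this parcellation belongs to.
#' @slot methodTag free-form tag recording the ROI definition method.
#' @slot seeds named integer vector of linear voxel indices (names are ROI
#'   labels); may be empty for atlas-derived parcellations.
#'
#' @seealso [Parcellation()], [greedyGrow()], [craddockCluster()],
#'   [generateRandomParcellation()]
#' @exportClass Parcellation
setClass("Parcellation",
         slots = c(labels = "array",
                   windowIndex = "integer",
                   methodTag = "character",
                   seeds = "integer"))

setValidity("Parcellation", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3D array")
  if (!is.integer(object@labels))
    return("labels must be an integer array")
  if (any(object@labels < 0L))
    return("labels must be nonnegative (0 = unassigned)")
  if (length(object@seeds)) {
    if (is.null(names(object@seeds)))
      return("seeds must be named by ROI label")
    if (any(object@seeds < 1L | object@seeds > length(object@labels)))
      return("seed indices out of grid bounds")
    lab <- object@labels[object@seeds]
    if (any(lab != as.integer(names(object@seeds))))
      return("each seed voxel must carry its own ROI label")
  }
  TRUE
})

#' Construct a Parcellation
#'
#' @param labels integer 3D array of ROI labels (0 = unassigned).
#' @param windowIndex time-window index (default 1).
#' @param methodTag method tag string.
#' @param seeds named integer vector of seed voxel linear indices.
#' @return A [Parcellation-class] object.
#' @export
Parcellation <- function(labels, windowIndex = 1L, methodTag = "",
                         seeds = integer(0)) {
  storage.mode(labels) <- "integer"
  if (length(seeds)) storage.mode(seeds) <- "integer"
  new("Parcellation", labels = labels, windowIndex = as.integer(windowIndex),
      methodTag = methodTag, seeds = seeds)
}

#' MultilayerNetwork: time-window layers of ROI nodes
#'
#' The node-reconfiguring multilayer network. Layers are non-overlapping
#' time windows; nodes are the ROIs of that window's parcellation; each
#' intralayer graph is complete with Pearson-correlation weights between
#' ROI mean time series; interlayer edges connect ROIs on consecutive
#' layers with the Jaccard index of their voxel sets (absent when the sets
#' are disjoint).
#'
#' @slot windows data.frame with columns \code{start}, \code{length}
#'   (sample indices, 1-based, half-open windows).
#' @slot nodes per-layer named list mapping ROI label to its voxel linear
#'   indices.
#' @slot series per-layer matrix (window length x number of ROIs) of ROI
#'   mean time series, columns named by label.
#' @slot intralayer per-layer symmetric correlation matrix over ROIs.
#' @slot interlayer list of length (number of layers - 1); element t is a
#'   data.frame \code{from}, \code{to}, \code{weight} of Jaccard edges
#'   between layers t and t+1.
#' @slot gridDim spatial grid dimensions the voxel indices refer to.
#'
#' @seealso [buildNetwork()], [stabilityScore()], [trajectory()]
#' @exportClass MultilayerNetwork
setClass("MultilayerNetwork",
         slots = c(windows = "data.frame",
                   nodes = "list",
                   series = "list",
                   intralayer = "list",
                   interlayer = "list",
                   gridDim = "integer"))

setValidity("MultilayerNetwork", function(object) {
  nl <- nrow(object@windows)
  if (length(object@nodes) != nl) return("one node set per layer required")
  if (length(object@series) != nl) return("one series matrix per layer required")
  if (length(object@intralayer) != nl) return("one intralayer graph per layer required")
  if (nl > 0 && length(object@interlayer) != nl - 1L)
    return("interlayer edges must connect consecutive layers only")
  for (e in object@interlayer) {
    if (!all(c("from", "to", "weight") %in% names(e)))
      return("interlayer edge frames need columns from, to, weight")
    if (nrow(e) && (any(e$weight <= 0) || any(e$weight > 1)))
      return("interlayer weights must lie in (0, 1]")
  }
  TRUE
})

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume: %dx%dx%d grid, %d time points (%.3g s/sample)\n",
              d[1], d[2], d[3], d[4], object@sampleInterval))
  cat(sprintf("  masked voxels: %d of %d\n", sum(object@mask), prod(d[1:3])))
})

setMethod("show", "Parcellation", function(object) {
  lab <- object@labels[object@labels > 0L]
  cat(sprintf("Parcellation [%s]: %d ROIs over %d voxels (window %d)\n",
              object@methodTag, length(unique(lab)), length(lab),
              object@windowIndex))
})

setMethod("show", "MultilayerNetwork", function(object) {
  nl <- nrow(object@windows)
  nn <- sum(vapply(object@nodes, length, 1L))
  ne <- sum(vapply(object@interlayer, nrow, 1L))
  cat(sprintf("MultilayerNetwork: %d layers, %d nodes, %d interlayer edges\n",
              nl, nn, ne))
})
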