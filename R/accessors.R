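#' @describeIn nTimepoints length of the time axis
#' @export
setMethod("nTimepoints", "VoxelVolume", function(x) dim(x@data)[4])

#' @describeIn maskIndices indices where the mask is TRUE
#' @export
setMethod("maskIndices", "VoxelVolume", function(x) which(x@mask))

#' @describeIn sampleInterval seconds per sample
#' @export
setMethod("sampleInterval", "VoxelVolume", function(x) x@sampleInterval)

#' @describeIn roiLabels positive labels, ascending
#' @export
setMethod("roiLabels", "Parcellation", function(x) {
  sort(unique(x@labels[x@labels > 0L]))
})

#' @describeIn roiVoxels linear indices of one ROI's voxels
#' @export
setMethod("roiVoxels", "Parcellation", function(x, label) {
  which(x@labels == as.integer(label))
})

#' @describeIn roiSizes voxel counts by label
#' @export
setMethod("roiSizes", "Parcellation", function(x) {
  lab <- x@labels[x@labels > 0L]
  tab <- table(lab)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
})

#' @describeIn roiSeeds seed voxel indices by label
#' @export
setMethod("roiSeeds", "Parcellation", function(x) x@seeds)

#' @describeIn nLayers number of time-window layers
#' @export
setMethod("nLayers", "MultilayerNetwork", function(x) nrow(x@windows))

#' @describeIn layerNodes voxel sets of one layer's ROIs
#' @export
setMethod("layerNodes", "MultilayerNetwork", function(x, layer) {
  x@nodes[[.checkLayer(x, layer)]]
})

#' @describeIn intralayerWeights complete correlation matrix of one layer
#' @export
setMethod("intralayerWeights", "MultilayerNetwork", function(x, layer) {
  x@intralayer[[.checkLayer(x, layer)]]
})

#' @describeIn interlayerWeights Jaccard edges from layer to layer + 1
#' @export
setMethod("interlayerWeights", "MultilayerNetwork", function(x, layer) {
  layer <- .checkLayer(x, layer)
  if (layer >= nLayers(x))
    stop("no interlayer edges beyond the last layer")
  x@interlayer[[layer]]
})

#' @describeIn networkWindows window table
#' @export
setMethod("networkWindows", "MultilayerNetwork", function(x) x@windows)

.checkLayer <- function(x, layer) {
  layer <- as.integer(layer)
  if (length(layer) != 1L || is.na(layer) || layer < 1L || layer > nLayers(x))
    stop(sprintf("layer must be in 1..%d", nLayers(x)))
  layer
}
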