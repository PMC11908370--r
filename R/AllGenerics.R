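#' Number of layers (time windows) of a multilayer network
#' @param x a [MultilayerNetwork-class] object
#' @return integer count
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' Number of time points
#' @param x a [VoxelVolume-class] object
#' @return integer count
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' Linear indices of masked voxels
#' @param x a [VoxelVolume-class] object
#' @return integer vector of linear indices into the 3D grid
#' @export
setGeneric("maskIndices", function(x) standardGeneric("maskIndices"))

#' Sampling interval in seconds
#' @param x a [VoxelVolume-class] object
#' @return numeric scalar
#' @export
setGeneric("sampleInterval", function(x) standardGeneric("sampleInterval"))

#' ROI labels present in a parcellation
#' @param x a [Parcellation-class] object
#' @return sorted integer vector of positive labels
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' Voxel indices of one ROI
#' @param x a [Parcellation-class] object
#' @param label ROI label
#' @return integer vector of linear voxel indices
#' @export
setGeneric("roiVoxels", function(x, label) standardGeneric("roiVoxels"))

#' Sizes of all ROIs
#' @param x a [Parcellation-class] object
#' @return named integer vector (names are labels)
#' @export
setGeneric("roiSizes", function(x) standardGeneric("roiSizes"))

#' Seed voxels of a region-grown parcellation
#' @param x a [Parcellation-class] object
#' @return named integer vector of linear voxel indices
#' @export
setGeneric("roiSeeds", function(x) standardGeneric("roiSeeds"))

#' Nodes of one layer
#' @param x a [MultilayerNetwork-class] object
#' @param layer layer index
#' @return named list mapping ROI label to voxel index vector
#' @export
setGeneric("layerNodes", function(x, layer) standardGeneric("layerNodes"))

#' Intralayer correlation weights of one layer
#' @param x a [MultilayerNetwork-class] object
#' @param layer layer index
#' @return symmetric numeric matrix with labels as dimnames
#' @export
setGeneric("intralayerWeights", function(x, layer)
  standardGeneric("intralayerWeights"))

#' Interlayer Jaccard edges between a layer and its successor
#' @param x a [MultilayerNetwork-class] object
#' @param layer layer index t; edges connect layers t and t+1
#' @return data.frame with columns from, to, weight
#' @export
setGeneric("interlayerWeights", function(x, layer)
  standardGeneric("interlayerWeights"))

#' Time windows backing the layers
#' @param x a [MultilayerNetwork-class] object
#' @return data.frame with columns start, length
#' @export
setGeneric("networkWindows", function(x) standardGeneric("networkWindows"))
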