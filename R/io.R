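#' Read a 4D NIfTI volume
#'
#' Loads a 4D NIfTI file into a [VoxelVolume-class]. The mask comes from a
#' companion NIfTI file when given, otherwise from a nonzero-variance
#' heuristic over voxel series. The voxel-to-world affine is retained for
#' write-back.
#'
#' @param path path to a 4D NIfTI file
#' @param maskPath optional path to a 3D NIfTI mask (nonzero = inside)
#' @param sampleInterval seconds per sample (default 0.1)
#' @return a [VoxelVolume-class]
#' @export
readVolume <- function(path, maskPath = NULL, sampleInterval = 0.1) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) != 4L)
    stop(sprintf("%s: expected 4 dimensions, found %d (%s)",
                 path, length(dim(arr)), paste(dim(arr), collapse = "x")))
  if (!all(is.finite(arr)))
    stop(sprintf("%s: non-finite values in the data", path))
  mask <- NULL
  if (!is.null(maskPath)) {
    mi <- RNifti::readNifti(maskPath)
    m <- array(as.vector(mi), dim = dim(mi))
    if (length(dim(m)) != 3L)
      stop(sprintf("%s: mask must be 3D, found %d dimensions",
                   maskPath, length(dim(m))))
    if (!identical(dim(m), dim(arr)[1:3]))
      stop(sprintf("mask shape %s does not match data spatial shape %s",
                   paste(dim(m), collapse = "x"),
                   paste(dim(arr)[1:3], collapse = "x")))
    mask <- array(m != 0, dim = dim(m))
  }
  VoxelVolume(arr, mask = mask, sampleInterval = sampleInterval,
              affine = unclass(RNifti::xform(img)))
}

#' Write a VoxelVolume (and its mask) as NIfTI
#'
#' @param volume a [VoxelVolume-class]
#' @param path output path for the 4D data
#' @param maskPath optional output path for the 3D mask
#' @return \code{path}, invisibly
#' @export
writeVolume <- function(volume, path, maskPath = NULL) {
  img <- RNifti::asNifti(volume@data)
  RNifti::sform(img) <- structure(volume@affine, code = 2L)
  RNifti::writeNifti(img, path)
  if (!is.null(maskPath)) {
    m <- RNifti::asNifti(array(as.integer(volume@mask),
                               dim = dim(volume@mask)))
    RNifti::sform(m) <- structure(volume@affine, code = 2L)
    RNifti::writeNifti(m, maskPath)
  }
  invisible(path)
}

#' Read an integer label volume as a Parcellation
#'
#' Generic entry point for static atlases: any 3D integer NIfTI label
#' volume (0 = unassigned) is accepted; no template registration is
#' performed.
#'
#' @param path path to a 3D NIfTI label volume
#' @param windowIndex window index to record (default 1)
#' @param methodTag method tag to record (default "atlas")
#' @return a [Parcellation-class]
#' @export
readParcellation <- function(path, windowIndex = 1L, methodTag = "atlas") {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) != 3L)
    stop(sprintf("%s: label volume must be 3D, found %d dimensions",
                 path, length(dim(arr))))
  Parcellation(array(as.integer(round(arr)), dim = dim(arr)),
               windowIndex = windowIndex, methodTag = methodTag)
}

#' Write a Parcellation as a NIfTI label volume
#'
#' @param parcellation a [Parcellation-class]
#' @param path output path
#' @param affine optional 4x4 voxel-to-world matrix
#' @return \code{path}, invisibly
#' @export
writeParcellation <- function(parcellation, path, affine = diag(4)) {
  img <- RNifti::asNifti(parcellation@labels)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Writes the 4D volume, the mask, one label volume per window, and a JSON
#' sidecar mapping window indices to label-volume filenames.
#'
#' @param dataset list with \code{volume} and \code{parcellations}, as
#'   returned by [generateReconfiguringDataset()]
#' @param dir output directory (created if needed)
#' @return the sidecar path, invisibly
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(dataset$volume, file.path(dir, "volume.nii.gz"),
              file.path(dir, "mask.nii.gz"))
  files <- character(length(dataset$parcellations))
  for (i in seq_along(dataset$parcellations)) {
    files[i] <- sprintf("planted_window%02d.nii.gz", i)
    writeParcellation(dataset$parcellations[[i]], file.path(dir, files[i]))
  }
  sidecar <- file.path(dir, "planted_parcellations.json")
  jsonlite::write_json(
    list(volume = "volume.nii.gz", mask = "mask.nii.gz",
         windows = stats::setNames(as.list(files),
                                   seq_along(files))),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Serialize a MultilayerNetwork to JSON
#'
#' Full-precision serialization of layers, node voxel sets, ROI mean
#' series, and intra-/interlayer weights; [readNetwork()] restores an
#' identical object.
#'
#' @param network a [MultilayerNetwork-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeNetwork <- function(network, path) {
  ser <- list(
    gridDim = network@gridDim,
    windows = as.list(network@windows),
    nodes = network@nodes,
    series = lapply(network@series, function(m)
      list(dim = dim(m), labels = colnames(m), values = as.vector(m))),
    intralayer = lapply(network@intralayer, function(m)
      list(dim = dim(m), labels = rownames(m), values = as.vector(m))),
    interlayer = lapply(network@interlayer, as.list))
  # 17 significant digits round-trip IEEE doubles exactly
  json <- jsonlite::toJSON(ser, digits = I(17), auto_unbox = FALSE,
                           na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Restore a MultilayerNetwork written by [writeNetwork()]
#'
#' @param path path to the JSON file
#' @return a [MultilayerNetwork-class]
#' @export
readNetwork <- function(path) {
  ser <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  series <- lapply(ser$series, function(x) {
    m <- matrix(as.numeric(unlist(x$values)), nrow = x$dim[1])
    colnames(m) <- as.character(unlist(x$labels))
    m
  })
  intra <- lapply(ser$intralayer, function(x) {
    m <- matrix(as.numeric(unlist(x$values)), nrow = x$dim[1])
    labs <- as.character(unlist(x$labels))
    dimnames(m) <- list(labs, labs)
    m
  })
  nodes <- lapply(ser$nodes, function(layer)
    lapply(layer, function(v) as.integer(unlist(v))))
  inter <- lapply(ser$interlayer, function(e)
    data.frame(from = as.integer(unlist(e$from)),
               to = as.integer(unlist(e$to)),
               weight = as.numeric(unlist(e$weight))))
  new("MultilayerNetwork",
      windows = data.frame(start = as.integer(unlist(ser$windows$start)),
                           length = as.integer(unlist(ser$windows$length))),
      nodes = nodes, series = series, intralayer = intra,
      interlayer = inter, gridDim = as.integer(unlist(ser$gridDim)))
}

#' Flat edge list of a MultilayerNetwork
#'
#' One row per edge: intralayer correlation edges (\code{edge_type =
#' "intra"}, both layers equal) and interlayer Jaccard edges
#' (\code{edge_type = "inter"}).
#'
#' @param network a [MultilayerNetwork-class]
#' @return data.frame with columns \code{layer_a}, \code{roi_a},
#'   \code{layer_b}, \code{roi_b}, \code{weight}, \code{edge_type}
#' @export
networkEdgeList <- function(network) {
  out <- list()
  for (t in seq_len(nLayers(network))) {
    C <- network@intralayer[[t]]
    if (nrow(C) >= 2L) {
      labs <- as.integer(rownames(C))
      ut <- which(upper.tri(C), arr.ind = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        layer_a = t, roi_a = labs[ut[, 1]],
        layer_b = t, roi_b = labs[ut[, 2]],
        weight = C[ut], edge_type = "intra")
    }
  }
  for (t in seq_along(network@interlayer)) {
    e <- network@interlayer[[t]]
    if (nrow(e))
      out[[length(out) + 1L]] <- data.frame(
        layer_a = t, roi_a = e$from, layer_b = t + 1L, roi_b = e$to,
        weight = e$weight, edge_type = "inter")
  }
  if (!length(out))
    return(data.frame(layer_a = integer(0), roi_a = integer(0),
                      layer_b = integer(0), roi_b = integer(0),
                      weight = numeric(0), edge_type = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full pipeline on one volume
#'
#' Orchestrates windowing, per-window ROI definition, single-voxel ROI
#' exclusion, multilayer network assembly, and the standard analytics, and
#' writes all artifacts plus a manifest into \code{outputDir}. Identical
#' inputs and seed give byte-identical outputs.
#'
#' Methods: the two greedy priorities grow from per-window ReHo seeds
#' (taken inside the ROIs of \code{atlas} if given, else inside a random
#' parcellation of \code{nRois} regions regenerated per window);
#' \code{"craddock"} runs NCUT spectral clustering per window;
#' \code{"random"} plants random region-grown parcels per window;
#' \code{"static"} replicates \code{atlas} on every layer, producing a
#' multiplex network.
#'
#' @param volume a [VoxelVolume-class], or a path to a 4D NIfTI file
#' @param outputDir output directory (created if needed)
#' @param method one of \code{"weighted_mean_consistency"},
#'   \code{"min_correlation"}, \code{"craddock"}, \code{"random"},
#'   \code{"static"}
#' @param atlas optional [Parcellation-class] (or path to a label volume)
#'   used as the static parcellation or the seed template
#' @param maskPath optional mask path when \code{volume} is a path
#' @param windowLength samples per window (default 80)
#' @param nRois ROI count for random parcels / seed templates (default 246)
#' @param lambda greedy regularization (default 100)
#' @param thresholdPercent greedy acceptance percentile N, \code{NULL} =
#'   off
#' @param edgeThreshold Craddock edge threshold (default 0.2)
#' @param seed RNG seed controlling all stochastic stages
#' @return the manifest as a list, invisibly
#' @export
runPipeline <- function(volume, outputDir,
                        method = c("weighted_mean_consistency",
                                   "min_correlation", "craddock",
                                   "random", "static"),
                        atlas = NULL, maskPath = NULL, windowLength = 80L,
                        nRois = 246L, lambda = 100,
                        thresholdPercent = NULL, edgeThreshold = 0.2,
                        seed = 1L) {
  method <- match.arg(method)
  if (is.character(volume))
    volume <- readVolume(volume, maskPath = maskPath)
  if (is.character(atlas)) atlas <- readParcellation(atlas)
  if (method == "static" && is.null(atlas))
    stop("static method requires an atlas parcellation")
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  stage <- "setup"
  on.exit({
    # a failed stage leaves a partial-output manifest behind
    if (!is.null(stage)) {
      jsonlite::write_json(
        list(package = "mlbrainnet", failedStage = stage,
             outputs = list.files(outputDir)),
        file.path(outputDir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE)
    }
  })
  tryCatch({
  stage <- "windowing"
  windows <- splitWindows(volume, windowLength)
  nl <- nrow(windows)

  stage <- "parcellation"
  parcs <- vector("list", nl)
  excluded <- integer(nl)
  for (t in seq_len(nl)) {
    w <- windows[t, ]
    p <- switch(method,
      random = generateRandomParcellation(volume@mask, nRois,
                                          windowIndex = t),
      static = {
        q <- atlas; q@windowIndex <- t; q
      },
      craddock = craddockCluster(volume, edgeThreshold = edgeThreshold,
                                 targetClusters = nRois, window = w,
                                 windowIndex = t),
      {
        template <- if (!is.null(atlas)) atlas else
          generateRandomParcellation(volume@mask, nRois, windowIndex = t)
        seeds <- selectRehoSeeds(volume, template, window = w)
        greedyGrow(volume, seeds, priority = method, lambda = lambda,
                   thresholdPercent = thresholdPercent, window = w,
                   windowIndex = t)
      })
    ex <- excludeSingleVoxelRois(p)
    parcs[[t]] <- ex$parcellation
    excluded[t] <- ex$excludedCount
    writeParcellation(parcs[[t]],
                      file.path(outputDir,
                                sprintf("parcellation_window%02d.nii.gz", t)),
                      affine = volume@affine)
  }

  stage <- "network"
  net <- buildNetwork(volume, parcs, windowLength)
  writeNetwork(net, file.path(outputDir, "network.json"))
  utils::write.table(networkEdgeList(net),
                     file.path(outputDir, "edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  stage <- "analytics"
  st <- stabilityScores(net)
  utils::write.csv(st, file.path(outputDir, "stability.csv"),
                   row.names = FALSE)
  cdf <- interlayerWeightCdf(net, "weights")
  utils::write.csv(cdf, file.path(outputDir, "interlayer_weight_cdf.csv"),
                   row.names = FALSE)
  if (!is.null(st) && nrow(st)) {
    mic <- mapply(function(t, l) meanIntralayerCorrelation(net, t, l),
                  st$layer, st$label)
    utils::write.csv(binnedCurve(st$stability, mic),
                     file.path(outputDir,
                               "mean_correlation_vs_stability.csv"),
                     row.names = FALSE)
  }
  if (nl >= 2L) {
    co <- lapply(seq_len(nl - 1L), function(t)
      consistencyCarryover(volume, parcs[[t]], windows[t, ],
                           windows[t + 1L, ]))
    carry <- data.frame(
      window = seq_len(nl - 1L),
      meanChange = vapply(co, `[[`, numeric(1), "meanChange"),
      relativeChange = vapply(co, `[[`, numeric(1), "relativeChange"))
    utils::write.csv(carry, file.path(outputDir, "carryover.csv"),
                     row.names = FALSE)
  }
  }, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))

  stage <- NULL   # all stages completed; write the final manifest
  manifest <- list(
    package = "mlbrainnet",
    version = as.character(utils::packageVersion("mlbrainnet")),
    method = method, seed = seed, windowLength = windowLength,
    nRois = nRois, lambda = lambda,
    thresholdPercent = if (is.null(thresholdPercent)) NA else
      thresholdPercent,
    edgeThreshold = edgeThreshold,
    voxelIndexing = "1-based column-major (R array order)",
    nLayers = nl, excludedSingleVoxelRois = excluded,
    outputs = unique(c(list.files(outputDir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
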