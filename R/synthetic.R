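#' Configuration for the synthetic reconfiguring dataset
#'
#' Bundles and validates the parameters of the planted-parcellation
#' generator. The defaults emulate the simulation design the clustering
#' algorithms assume: region-grown random parcels, independent white-noise
#' seed signals, and a distance-decaying signal/noise mixture with a
#' zero-mean Gaussian kernel of variance 5 (voxel units squared).
#'
#' @param gridShape integer triple: voxels per axis
#' @param nRois number of planted ROIs (at most the number of masked voxels)
#' @param nTimepoints total number of time points across all windows
#' @param nWindows number of equal-length time windows; must divide
#'   \code{nTimepoints}
#' @param gaussianVariance variance of the Gaussian mixing kernel G
#'   (default 5)
#' @param noiseAmplitude standard deviation of the voxel-specific noise
#'   series n(t) relative to the unit-variance seed signals (default 1,
#'   the plain white-noise recipe; smaller values give a low-noise regime)
#' @param noiseSeed RNG seed controlling all randomness of the generator
#' @param reconfigureFraction fraction in \[0, 1\] of ROI seeds relocated
#'   between consecutive windows
#' @return a validated list of class \code{"SyntheticConfig"}
#' @examples
#' cfg <- syntheticConfig(gridShape = c(8, 8, 8), nRois = 5,
#'                        nTimepoints = 160, nWindows = 2)
#' @export
syntheticConfig <- function(gridShape = c(10L, 10L, 10L), nRois = 10L,
                            nTimepoints = 240L, nWindows = 3L,
                            gaussianVariance = 5, noiseAmplitude = 1,
                            noiseSeed = 1L,
                            reconfigureFraction = 0.2) {
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L, all(gridShape >= 1L))
  if (nRois > prod(gridShape))
    stop("nRois exceeds the number of masked voxels")
  if (gaussianVariance <= 0) stop("gaussianVariance must be positive")
  if (reconfigureFraction < 0 || reconfigureFraction > 1)
    stop("reconfigureFraction must lie in [0, 1]")
  if (nWindows < 1L) stop("nWindows must be at least 1")
  if (nTimepoints %% nWindows != 0L)
    stop("nTimepoints must be a multiple of the window count")
  if (noiseAmplitude < 0) stop("noiseAmplitude must be nonnegative")
  structure(list(gridShape = gridShape, nRois = as.integer(nRois),
                 nTimepoints = as.integer(nTimepoints),
                 nWindows = as.integer(nWindows),
                 gaussianVariance = gaussianVariance,
                 noiseAmplitude = noiseAmplitude,
                 noiseSeed = as.integer(noiseSeed),
                 reconfigureFraction = reconfigureFraction),
            class = "SyntheticConfig")
}

#' Random region-grown parcellation
#'
#' Plants \code{nRois} seeds uniformly at random (without replacement) over
#' the masked voxels, then grows all ROIs in rounds: at each round every
#' ROI absorbs all currently unassigned face-neighbors of the voxels it
#' held at the start of the round. ROIs are processed in ascending label
#' order, so a voxel claimed by several ROIs in the same round goes to the
#' lowest label. Growth stops when every masked voxel is assigned, which
#' produces approximately spherical, 6-connected ROIs partitioning the mask.
#'
#' @param mask logical 3D array of usable voxels
#' @param nRois number of ROIs; at most \code{sum(mask)}
#' @param seed optional RNG seed; \code{NULL} uses the current RNG stream
#' @param windowIndex window index recorded on the result
#' @return a [Parcellation-class] with seeds recorded
#' @examples
#' p <- generateRandomParcellation(array(TRUE, c(6, 6, 1)), 2, seed = 7)
#' roiSizes(p)
#' @export
generateRandomParcellation <- function(mask, nRois, seed = NULL,
                                       windowIndex = 1L) {
  if (!is.logical(mask)) mask <- array(mask != 0, dim = dim(mask))
  idx <- which(mask)
  if (!length(idx)) stop("mask contains no voxels")
  nRois <- as.integer(nRois)
  if (nRois < 1L || nRois > length(idx))
    stop("nRois must be between 1 and the number of masked voxels")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sort(sample(idx, nRois))
  names(seeds) <- seq_len(nRois)
  .growFromSeeds(mask, seeds, windowIndex, "random")
}

# Round-based region growing shared by the random parcellation and the
# reconfiguring generator. `seeds`: named linear indices (names = labels).
.growFromSeeds <- function(mask, seeds, windowIndex, methodTag) {
  dim3 <- dim(mask)
  labels <- array(0L, dim = dim3)
  labels[seeds] <- as.integer(names(seeds))
  frontier <- lapply(seeds, identity)   # per-ROI voxels added last round
  repeat {
    grew <- FALSE
    newFrontier <- vector("list", length(frontier))
    names(newFrontier) <- names(frontier)
    for (li in seq_along(frontier)) {
      fv <- frontier[[li]]
      if (!length(fv)) { newFrontier[[li]] <- integer(0); next }
      nb <- .neighborMatrix(fv, dim3, mask)
      nb <- unique(nb[!is.na(nb)])
      nb <- nb[labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- as.integer(names(frontier)[li])
        grew <- TRUE
      }
      newFrontier[[li]] <- nb
    }
    if (!grew) break
    frontier <- newFrontier
  }
  Parcellation(labels, windowIndex = windowIndex, methodTag = methodTag,
               seeds = seeds)
}

#' Synthetic voxel time series from a planted parcellation
#'
#' Each ROI seed voxel receives an independent standard white-noise series
#' x(t). Every other voxel at Euclidean distance d from its ROI's seed
#' receives the mixture y(t) = w x(t) + (1 - w) n(t) with mixing weight
#' w = G(d)/G(0) = exp(-d^2 / (2 sigma^2)), where G is the zero-mean
#' Gaussian density with variance sigma^2 and n(t) is voxel-specific white
#' noise. Voxels near a seed therefore correlate strongly with it, and the
#' correlation decays with distance, giving the planted ROIs the
#' within-over-between correlation structure that the clustering
#' algorithms look for.
#'
#' @param parcellation a [Parcellation-class] with seeds for every ROI
#' @param nTimepoints number of time points (>= 2)
#' @param gaussianVariance variance of the mixing kernel (default 5)
#' @param noiseAmplitude standard deviation of the voxel-specific noise
#'   n(t) (default 1)
#' @param seed optional RNG seed; \code{NULL} uses the current stream
#' @param sampleInterval seconds per sample for the result (default 0.1)
#' @return a [VoxelVolume-class] whose mask is the set of assigned voxels
#' @export
generateVoxelTimeseries <- function(parcellation, nTimepoints,
                                    gaussianVariance = 5,
                                    noiseAmplitude = 1, seed = NULL,
                                    sampleInterval = 0.1) {
  nTimepoints <- as.integer(nTimepoints)
  if (nTimepoints < 2L) stop("nTimepoints must be at least 2")
  if (gaussianVariance <= 0) stop("gaussianVariance must be positive")
  labels <- parcellation@labels
  dim3 <- dim(labels)
  seeds <- parcellation@seeds
  labs <- roiLabels(parcellation)
  if (!all(as.character(labs) %in% names(seeds)))
    stop("missing seed record for at least one ROI")
  if (!is.null(seed)) set.seed(seed)

  # seed signals, drawn in label order for reproducibility
  X <- matrix(stats::rnorm(nTimepoints * length(labs)), nrow = nTimepoints)
  colnames(X) <- as.character(labs)

  mask <- labels > 0L
  vox <- which(mask)
  co <- .coordsOf(vox, dim3)
  seedIdx <- seeds[as.character(labels[vox])]
  seedCo <- .coordsOf(seedIdx, dim3)
  d2 <- rowSums((co - seedCo)^2)
  w <- exp(-d2 / (2 * gaussianVariance))

  noise <- matrix(stats::rnorm(nTimepoints * length(vox),
                               sd = noiseAmplitude),
                  nrow = nTimepoints)
  sig <- X[, as.character(labels[vox]), drop = FALSE]
  Y <- sweep(sig, 2L, w, "*") + sweep(noise, 2L, 1 - w, "*")
  # seeds carry x(t) exactly: w = 1 makes the noise term vanish identically

  data <- array(0, dim = c(dim3, nTimepoints))
  flat <- matrix(0, nrow = prod(dim3), ncol = nTimepoints)
  flat[vox, ] <- t(Y)
  data[] <- flat
  VoxelVolume(data, mask = array(mask, dim = dim3),
              sampleInterval = sampleInterval)
}

#' Multi-window dataset with reconfiguring planted parcellations
#'
#' Generates one planted random parcellation per time window and an
#' independent synthetic volume for each window, concatenated along the
#' time axis. Between consecutive windows a fraction of the ROI seeds is
#' relocated to random masked voxels and the parcellation regrown from the
#' updated seed set, so the planted voxel groups reorganize over time while
#' retaining their within-window correlation structure.
#'
#' @param config a \code{SyntheticConfig} from [syntheticConfig()]
#' @param mask optional logical 3D array; default is the full grid
#' @return list with elements \code{volume} (a [VoxelVolume-class]) and
#'   \code{parcellations} (one planted [Parcellation-class] per window)
#' @examples
#' cfg <- syntheticConfig(gridShape = c(6, 6, 6), nRois = 4,
#'                        nTimepoints = 80, nWindows = 2, noiseSeed = 3)
#' ds <- generateReconfiguringDataset(cfg)
#' length(ds$parcellations)
#' @export
generateReconfiguringDataset <- function(config, mask = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(mask)) mask <- array(TRUE, dim = config$gridShape)
  set.seed(config$noiseSeed)
  L <- config$nTimepoints %/% config$nWindows
  parcs <- vector("list", config$nWindows)
  volumes <- vector("list", config$nWindows)
  parcs[[1L]] <- generateRandomParcellation(mask, config$nRois,
                                            windowIndex = 1L)
  for (wi in seq_len(config$nWindows)) {
    if (wi > 1L) {
      seeds <- parcs[[wi - 1L]]@seeds
      nMove <- round(config$reconfigureFraction * length(seeds))
      if (nMove > 0L) {
        move <- sample(seq_along(seeds), nMove)
        pool <- setdiff(which(mask), seeds)
        seeds[move] <- sample(pool, nMove)
      }
      parcs[[wi]] <- .growFromSeeds(mask, seeds, wi, "random")
    }
    volumes[[wi]] <- generateVoxelTimeseries(parcs[[wi]], L,
                                             config$gaussianVariance,
                                             config$noiseAmplitude)
  }
  dim3 <- dim(mask)
  data <- array(0, dim = c(dim3, config$nTimepoints))
  flat <- matrix(0, nrow = prod(dim3), ncol = config$nTimepoints)
  for (wi in seq_len(config$nWindows)) {
    cols <- ((wi - 1L) * L + 1L):(wi * L)
    flat[, cols] <- .flatData(volumes[[wi]])
  }
  data[] <- flat
  list(volume = VoxelVolume(data, mask = mask),
       parcellations = parcs)
}
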