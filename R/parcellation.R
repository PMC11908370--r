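#' ReHo-based seed selection from an atlas
#'
#' Computes regional homogeneity for every masked voxel of each atlas ROI
#' and returns the voxel with the highest ReHo per ROI. Using one seed per
#' atlas region keeps the seeds spread over the whole masked space and
#' fixes the number of grown ROIs to the atlas ROI count. Atlas ROIs with
#' no masked voxels are skipped with a warning. Ties are broken by the
#' lowest linear voxel index.
#'
#' @param volume a [VoxelVolume-class], typically windowed to one time
#'   window
#' @param atlas a [Parcellation-class] used as the seed template
#' @param window optional window restriction (\code{start}, \code{length})
#' @return named integer vector of seed linear indices (names = atlas
#'   labels)
#' @export
selectRehoSeeds <- function(volume, atlas, window = NULL) {
  dim3 <- dim(volume@mask)
  labs <- roiLabels(atlas)
  if (!length(labs)) stop("atlas parcellation is empty")
  seeds <- integer(0)
  for (l in labs) {
    vox <- roiVoxels(atlas, l)
    vox <- vox[volume@mask[vox]]
    if (!length(vox)) {
      warning(sprintf("atlas ROI %d has no masked voxels; skipped", l))
      next
    }
    reho <- vapply(vox, function(v)
      regionalHomogeneity(volume, v, window), numeric(1))
    best <- vox[which.max(reho)]   # which.max takes the first (lowest index)
    seeds[as.character(l)] <- best
  }
  seeds
}

#' Greedy region-growing parcellation
#'
#' Grows ROIs voxel by voxel from the given seeds. A queue holds all pairs
#' of an ROI and an unassigned face-neighboring voxel; at each step the
#' pair with the highest priority is popped and, if thresholding passes,
#' the voxel joins the ROI and the queue is updated (newly adjacent voxels
#' enter, all pairs involving the assigned voxel leave). Two priority
#' functions are available:
#'
#' \describe{
#'   \item{\code{"weighted_mean_consistency"}}{the size-weighted mean
#'     spatial consistency over all ROIs, evaluated as if the candidate
#'     were already assigned, minus \code{lambda} times the sum of squared
#'     ROI sizes over the squared total size. The first term drives
#'     functional homogeneity; the second regularizes the ROI size
#'     distribution (default \code{lambda} = 100).}
#'   \item{\code{"min_correlation"}}{the lowest Pearson correlation between
#'     the candidate and any voxel already in the ROI; needs no
#'     regularization because it does not favor small ROIs.}
#' }
#'
#' With \code{thresholdPercent = N} (default off), a popped candidate is
#' accepted only if its average correlation to the target ROI is among the
#' N\% highest such values over all pairs currently queued; rejected pairs
#' never re-enter the queue. Stringent thresholds can leave voxels
#' unassigned and seeds stuck as single-voxel ROIs. Because growth is one
#' face-adjacent voxel at a time, every ROI is 6-connected.
#'
#' Ties in priority are broken by ascending (ROI label, voxel linear
#' index), making the algorithm fully deterministic.
#'
#' @param volume a [VoxelVolume-class]
#' @param seeds named integer vector of distinct masked seed voxels
#'   (names become ROI labels); an unnamed vector is labeled 1..n
#' @param priority \code{"weighted_mean_consistency"} or
#'   \code{"min_correlation"}
#' @param lambda regularization weight for the weighted-mean-consistency
#'   priority (default 100)
#' @param thresholdPercent N in (0, 100\]; \code{NULL} disables
#'   thresholding
#' @param window optional window restriction (\code{start}, \code{length})
#' @param windowIndex window index recorded on the result
#' @return a [Parcellation-class]; voxels rejected by thresholding or
#'   unreachable from any seed stay unassigned
#' @export
greedyGrow <- function(volume, seeds,
                       priority = c("weighted_mean_consistency",
                                    "min_correlation"),
                       lambda = 100, thresholdPercent = NULL,
                       window = NULL, windowIndex = 1L) {
  priority <- match.arg(priority)
  if (!length(seeds)) stop("seed set must be non-empty")
  if (anyDuplicated(seeds)) stop("seeds must be pairwise distinct")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (!is.null(thresholdPercent) &&
      (thresholdPercent <= 0 || thresholdPercent > 100))
    stop("thresholdPercent must lie in (0, 100]")
  seeds <- as.integer(seeds)
  if (is.null(names(seeds))) names(seeds) <- seq_along(seeds)
  dim3 <- dim(volume@mask)
  if (!all(volume@mask[seeds])) stop("all seeds must be masked")

  maskIdx <- which(volume@mask)
  V <- length(maskIdx)
  pos <- integer(prod(dim3))            # grid index -> masked position
  pos[maskIdx] <- seq_len(V)
  Z <- .standardize(.seriesMatrix(volume, maskIdx, window))
  .warnConstant(attr(Z, "nConstant"), "greedyGrow")
  nbM <- .neighborMatrix(maskIdx, dim3, volume@mask)   # V x 6, grid indices

  nR <- length(seeds)
  labNames <- names(seeds)
  assign <- integer(V)                  # 0 = unassigned, else ROI 1..nR
  sizes <- integer(nR)
  pairSum <- numeric(nR)                # sum of pairwise correlations in ROI
  S <- matrix(0, nrow = nrow(Z), ncol = nR)  # per-ROI sum of z-columns
  members <- vector("list", nR)
  for (r in seq_len(nR)) {
    p <- pos[seeds[r]]
    assign[p] <- r
    sizes[r] <- 1L
    S[, r] <- Z[, p]
    members[[r]] <- p
  }

  # queue state, one entry per (ROI, candidate voxel) pair
  qRoi <- integer(0); qVox <- integer(0); qMin <- numeric(0)
  rejected <- vector("list", nR)        # voxels rejected per ROI
  for (r in seq_len(nR)) rejected[[r]] <- integer(0)

  pushCandidates <- function(r, newVox) {
    # newVox: masked positions newly adjacent to ROI r
    newVox <- newVox[assign[newVox] == 0L]
    newVox <- setdiff(newVox, c(qVox[qRoi == r], rejected[[r]]))
    if (!length(newVox)) return()
    if (priority == "min_correlation") {
      mc <- vapply(newVox, function(p)
        min(crossprod(Z[, members[[r]], drop = FALSE], Z[, p])), numeric(1))
    } else {
      mc <- rep(NA_real_, length(newVox))
    }
    qRoi <<- c(qRoi, rep.int(r, length(newVox)))
    qVox <<- c(qVox, newVox)
    qMin <<- c(qMin, mc)
  }

  for (r in seq_len(nR)) {
    nb <- nbM[pos[seeds[r]], ]
    pushCandidates(r, pos[nb[!is.na(nb)]])
  }

  totalAssigned <- nR
  needAvg <- priority == "weighted_mean_consistency" ||
    !is.null(thresholdPercent)
  while (length(qVox)) {
    # average correlation of each queued candidate to its ROI (also the
    # ROI's hypothetical consistency contribution numerator)
    if (needAvg) {
      aSum <- colSums(Z[, qVox, drop = FALSE] * S[, qRoi, drop = FALSE])
      avg <- aSum / sizes[qRoi]
    }

    if (priority == "weighted_mean_consistency") {
      # size-weighted mean consistency term: each ROI I' contributes
      # |I'| * phi(I') = 2 * pairSum / (|I'| - 1); single-voxel ROIs
      # contribute 0 (phi undefined for size 1)
      contrib <- ifelse(sizes > 1L, 2 * pairSum / (sizes - 1L), 0)
      sTot <- sum(contrib)
      qSq <- sum(sizes^2)
      newContrib <- 2 * (pairSum[qRoi] + aSum) / sizes[qRoi]
      tot1 <- totalAssigned + 1L
      pv <- (sTot - contrib[qRoi] + newContrib) / tot1 -
        lambda * (qSq - sizes[qRoi]^2 + (sizes[qRoi] + 1L)^2) / tot1^2
    } else {
      pv <- qMin
    }

    # deterministic pop: max priority, ties by (label, voxel linear index)
    ord <- order(-pv, as.integer(labNames)[qRoi], maskIdx[qVox])
    k <- ord[1L]
    r <- qRoi[k]; p <- qVox[k]

    accepted <- TRUE
    if (!is.null(thresholdPercent)) {
      accepted <- thresholdAccept(avg[k], avg, thresholdPercent)
    }

    if (!accepted) {
      rejected[[r]] <- c(rejected[[r]], p)
      qRoi <- qRoi[-k]; qVox <- qVox[-k]; qMin <- qMin[-k]
      next
    }

    # assign p to ROI r
    assign[p] <- r
    if (needAvg) pairSum[r] <- pairSum[r] + aSum[k]
    S[, r] <- S[, r] + Z[, p]
    sizes[r] <- sizes[r] + 1L
    totalAssigned <- totalAssigned + 1L
    members[[r]] <- c(members[[r]], p)

    # drop every queue entry referring to p; update min-correlations of
    # ROI r's remaining candidates against the new member
    drop <- qVox == p
    if (any(drop)) {
      qRoi <- qRoi[!drop]; qVox <- qVox[!drop]; qMin <- qMin[!drop]
    }
    if (priority == "min_correlation") {
      upd <- which(qRoi == r)
      if (length(upd)) {
        cc <- as.numeric(crossprod(Z[, qVox[upd], drop = FALSE], Z[, p]))
        qMin[upd] <- pmin(qMin[upd], cc)
      }
    }
    nb <- nbM[p, ]
    pushCandidates(r, pos[nb[!is.na(nb)]])
  }

  labels <- array(0L, dim = dim3)
  labels[maskIdx[assign > 0L]] <-
    as.integer(labNames)[assign[assign > 0L]]
  sd <- seeds
  names(sd) <- labNames
  Parcellation(labels, windowIndex = windowIndex,
               methodTag = paste0("greedy_", priority), seeds = sd)
}

#' Top-N-percent acceptance test for greedy growth
#'
#' A candidate passes when its average correlation to the target ROI is
#' among the N\% highest values of the reference distribution, i.e. at
#' least as large as the floor(N/100 * n)-th largest reference value (at
#' least the largest when N is very small). N = 100 disables filtering.
#'
#' @param candidateMeanCorrelation the candidate's average correlation to
#'   its ROI
#' @param referenceDistribution numeric vector of reference values
#'   (average correlations of all currently queued pairs)
#' @param thresholdPercent N in (0, 100]
#' @return logical
#' @examples
#' thresholdAccept(0.85, seq(0.1, 1, by = 0.1), 30)  # 0.85 >= 0.8: TRUE
#' @export
thresholdAccept <- function(candidateMeanCorrelation, referenceDistribution,
                            thresholdPercent) {
  if (thresholdPercent <= 0 || thresholdPercent > 100)
    stop("thresholdPercent must lie in (0, 100]")
  if (!length(referenceDistribution))
    stop("reference distribution must be non-empty")
  if (thresholdPercent >= 100) return(TRUE)
  n <- length(referenceDistribution)
  k <- max(1L, floor(thresholdPercent / 100 * n))
  cut <- sort(referenceDistribution, decreasing = TRUE)[k]
  candidateMeanCorrelation >= cut
}

#' Weighted-mean-consistency priority of a candidate assignment
#'
#' Evaluates the global priority value for assigning \code{candidate} to
#' the ROI labeled \code{label}: the size-weighted mean spatial consistency
#' over all ROIs of the parcellation, computed as if the candidate were
#' already a member, minus \code{lambda} times the sum of squared ROI sizes
#' divided by the squared total assigned size. Exposed mainly for testing
#' and illustration; [greedyGrow()] evaluates the same quantity
#' incrementally.
#'
#' @param volume a [VoxelVolume-class]
#' @param parcellation the current [Parcellation-class] state
#' @param label ROI label receiving the candidate
#' @param candidate linear voxel index, unassigned and face-adjacent to the
#'   ROI
#' @param lambda regularization weight (default 100)
#' @param window optional window restriction
#' @return the priority value (higher is better)
#' @export
priorityWeightedMeanConsistency <- function(volume, parcellation, label,
                                            candidate, lambda = 100,
                                            window = NULL) {
  labels <- parcellation@labels
  if (labels[candidate] != 0L) stop("candidate voxel is already assigned")
  labels[candidate] <- as.integer(label)
  labs <- sort(unique(labels[labels > 0L]))
  sizes <- numeric(length(labs))
  phiw <- numeric(length(labs))
  for (i in seq_along(labs)) {
    vox <- which(labels == labs[i])
    sizes[i] <- length(vox)
    phiw[i] <- if (sizes[i] > 1L)
      sizes[i] * spatialConsistency(volume, vox, window) else 0
  }
  tot <- sum(sizes)
  sum(phiw) / tot - lambda * sum(sizes^2) / tot^2
}

#' Minimum-correlation priority of a candidate assignment
#'
#' The lowest Pearson correlation between the candidate voxel's time
#' series and the series of any voxel already assigned to the ROI.
#'
#' @param volume a [VoxelVolume-class]
#' @param roiVoxels integer vector of the ROI's current voxels (non-empty)
#' @param candidate linear voxel index of the candidate
#' @param window optional window restriction
#' @return the minimum correlation (higher is better)
#' @export
priorityMinCorrelation <- function(volume, roiVoxels, candidate,
                                   window = NULL) {
  if (!length(roiVoxels)) stop("ROI voxel set must be non-empty")
  Z <- .standardize(.seriesMatrix(volume, c(candidate, roiVoxels), window))
  min(crossprod(Z[, -1L, drop = FALSE], Z[, 1L]))
}

#' Remove single-voxel ROIs
#'
#' ROIs of size 1 usually reflect seeds whose growth was blocked by
#' thresholding rather than genuine functional units; they are set to
#' unassigned and their count reported.
#'
#' @param parcellation a [Parcellation-class]
#' @return list with \code{parcellation} (single-voxel ROIs removed) and
#'   \code{excludedCount}
#' @export
excludeSingleVoxelRois <- function(parcellation) {
  sz <- roiSizes(parcellation)
  singles <- as.integer(names(sz)[sz == 1L])
  labels <- parcellation@labels
  if (length(singles)) labels[labels %in% singles] <- 0L
  seeds <- parcellation@seeds
  if (length(seeds))
    seeds <- seeds[!(as.integer(names(seeds)) %in% singles)]
  list(parcellation = Parcellation(labels, parcellation@windowIndex,
                                   parcellation@methodTag, seeds),
       excludedCount = length(singles))
}

#' Consistency-ranked filtering of a static parcellation
#'
#' Ranks the atlas ROIs by spatial consistency in the given window and
#' retains them in rank order while the cumulative voxel count stays
#' within \code{voxelBudget}; the first ROI that would overflow the budget
#' stops the fill. This builds the filtered-multiplex baseline in which a
#' static atlas keeps only its most functionally homogeneous regions.
#'
#' @param volume a [VoxelVolume-class]
#' @param atlas a [Parcellation-class]
#' @param voxelBudget maximum total number of voxels retained
#' @param window optional window restriction
#' @return a [Parcellation-class] containing the retained ROIs
#' @export
filterStaticParcellation <- function(volume, atlas, voxelBudget,
                                     window = NULL) {
  labs <- roiLabels(atlas)
  phi <- vapply(labs, function(l) {
    vox <- roiVoxels(atlas, l)
    if (length(vox) < 2L) return(-Inf)
    spatialConsistency(volume, vox, window)
  }, numeric(1))
  ord <- labs[order(-phi, labs)]
  sizes <- roiSizes(atlas)
  keep <- integer(0)
  used <- 0L
  for (l in ord) {
    s <- sizes[[as.character(l)]]
    if (used + s > voxelBudget) break
    keep <- c(keep, l)
    used <- used + s
  }
  labels <- atlas@labels
  labels[!(labels %in% keep)] <- 0L
  if (!length(keep))
    warning("voxel budget below the smallest ROI; empty parcellation")
  seeds <- atlas@seeds
  if (length(seeds))
    seeds <- seeds[as.integer(names(seeds)) %in% keep]
  Parcellation(labels, atlas@windowIndex,
               paste0(atlas@methodTag, "_filtered"), seeds)
}
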