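test_that("greedy growth recovers planted blocks exactly with either priority", {
  vol <- twoBlockVolume()
  seeds <- c("1" = 1L, "2" = 3L)       # one seed inside each block
  planted <- list(`1` = c(1L, 2L, 5L, 6L), `2` = c(3L, 4L, 7L, 8L))
  for (pr in c("weighted_mean_consistency", "min_correlation")) {
    p <- greedyGrow(vol, seeds, priority = pr)
    for (l in 1:2)
      expect_equal(jaccardOracle(roiVoxels(p, l), planted[[as.character(l)]]),
                   1, info = pr)
  }
})

test_that("greedy growth assigns every reachable voxel when unthresholded", {
  # globally identical series: uniform priorities, full assignment
  s <- rnorm(20)
  vol <- volumeFromSeries(matrix(s, 20, 12), c(4, 3, 1))
  p <- greedyGrow(vol, c("1" = 1L, "2" = 12L))
  expect_equal(sum(roiSizes(p)), 12L)
  for (l in 1:2)
    expect_true(floodFillConnected(roiVoxels(p, l), c(4, 3, 1)))

  # a masked island unreachable from the seed stays unassigned
  mask <- array(TRUE, c(5, 1, 1)); mask[4] <- FALSE
  set.seed(2)
  vol2 <- VoxelVolume(array(rnorm(5 * 20), c(5, 1, 1, 20)), mask = mask)
  p2 <- greedyGrow(vol2, c("1" = 1L))
  expect_equal(sort(roiVoxels(p2, 1)), 1:3)
  expect_equal(p2@labels[5], 0L)
})

test_that("greedy growth is deterministic", {
  cfg <- syntheticConfig(gridShape = c(5, 5, 2), nRois = 3,
                         nTimepoints = 40, nWindows = 1, noiseSeed = 4)
  ds <- generateReconfiguringDataset(cfg)
  seeds <- roiSeeds(ds$parcellations[[1]])
  a <- greedyGrow(ds$volume, seeds, priority = "min_correlation")
  b <- greedyGrow(ds$volume, seeds, priority = "min_correlation")
  expect_identical(a@labels, b@labels)
})

test_that("the exposed global priority ranks candidates like the grower", {
  # the incremental evaluation inside greedyGrow must order candidates
  # exactly as the full formula does; check the very first assignment
  cfg <- syntheticConfig(gridShape = c(4, 4, 1), nRois = 2,
                         nTimepoints = 30, nWindows = 1, noiseSeed = 6)
  ds <- generateReconfiguringDataset(cfg)
  vol <- ds$volume
  seeds <- roiSeeds(ds$parcellations[[1]])
  start <- Parcellation({
    lb <- array(0L, c(4, 4, 1)); lb[seeds] <- as.integer(names(seeds)); lb
  }, seeds = seeds)
  # enumerate all (ROI, neighbor) pairs and their global Eq-style priority
  best <- NULL; bestPv <- -Inf
  for (l in roiLabels(start)) {
    vox <- roiVoxels(start, l)
    for (v in setdiff(which(start@labels == 0L), vox)) {
      co <- arrayInd(v, c(4, 4, 1)); cs <- arrayInd(vox, c(4, 4, 1))
      if (min(abs(co[1] - cs[, 1]) + abs(co[2] - cs[, 2])) != 1) next
      pv <- priorityWeightedMeanConsistency(vol, start, l, v, lambda = 100)
      if (pv > bestPv) { bestPv <- pv; best <- c(l, v) }
    }
  }
  grown <- greedyGrow(vol, seeds, priority = "weighted_mean_consistency")
  # the winning voxel must belong to the winning ROI in the final result
  expect_equal(grown@labels[best[2]], best[1])
})

test_that("weighted-mean-consistency priority matches hand evaluation", {
  # single ROI, lambda 0: the priority is the hypothetical consistency
  s <- seriesWithCorrelation(diag(3) * 0.4 + 0.6, 30, seed = 2)
  vol <- volumeFromSeries(cbind(s, rnorm(30)), c(4, 1, 1))
  start <- Parcellation(array(c(1L, 1L, 0L, 0L), c(4, 1, 1)))
  pv0 <- priorityWeightedMeanConsistency(vol, start, 1, 3L, lambda = 0)
  expect_equal(pv0, spatialConsistency(vol, 1:3))

  # two ROIs of sizes 2 and 2, lambda 100: direct formula evaluation
  start2 <- Parcellation(array(c(1L, 1L, 0L, 2L, 2L), c(5, 1, 1)))
  set.seed(14)
  vol2 <- volumeFromSeries(matrix(rnorm(30 * 5), 30), c(5, 1, 1))
  pv <- priorityWeightedMeanConsistency(vol2, start2, 1, 3L, lambda = 100)
  phi1 <- spatialConsistency(vol2, 1:3)          # ROI 1 with the candidate
  phi2 <- spatialConsistency(vol2, 4:5)
  hand <- (3 * phi1 + 2 * phi2) / 5 - 100 * (3^2 + 2^2) / 5^2
  expect_equal(pv, hand)
})

test_that("minimum-correlation priority is the worst member correlation", {
  # construct exact correlations corr(c,a) = 0.9, corr(c,b) = 0.2
  C <- matrix(c(1, 0.9, 0.2,
                0.9, 1, 0.1,
                0.2, 0.1, 1), 3, byrow = TRUE)
  s <- seriesWithCorrelation(C, 40, seed = 3)
  vol <- volumeFromSeries(s, c(3, 1, 1))   # voxel1 = c, voxel2 = a, voxel3 = b
  expect_equal(priorityMinCorrelation(vol, c(2L, 3L), 1L), 0.2)
  expect_equal(priorityMinCorrelation(vol, 2L, 1L), 0.9)
  # single identical voxel: priority 1
  s1 <- rnorm(20)
  vol2 <- volumeFromSeries(cbind(s1, s1), c(2, 1, 1))
  expect_equal(priorityMinCorrelation(vol2, 2L, 1L), 1.0)
  # growing the ROI can only lower the priority
  expect_lte(priorityMinCorrelation(vol, c(2L, 3L), 1L),
             priorityMinCorrelation(vol, 2L, 1L))
})

test_that("percentile thresholding accepts exactly the top N%", {
  expect_true(thresholdAccept(0.0, runif(20), 100))      # N = 100: always
  ref <- seq(0.1, 1.0, by = 0.1)
  expect_true(thresholdAccept(0.80, ref, 30))            # at the cut
  expect_true(thresholdAccept(0.85, ref, 30))
  expect_false(thresholdAccept(0.79, ref, 30))
  expect_false(thresholdAccept(0.05, ref, 99))           # below the minimum
  expect_error(thresholdAccept(0.5, ref, 0), "thresholdPercent")
  expect_error(thresholdAccept(0.5, numeric(0), 50), "non-empty")
})

test_that("stringent thresholding leaves voxels unassigned", {
  cfg <- syntheticConfig(gridShape = c(6, 6, 1), nRois = 3,
                         nTimepoints = 40, nWindows = 1, noiseSeed = 10)
  ds <- generateReconfiguringDataset(cfg)
  seeds <- roiSeeds(ds$parcellations[[1]])
  pFree <- greedyGrow(ds$volume, seeds, priority = "min_correlation")
  pTight <- greedyGrow(ds$volume, seeds, priority = "min_correlation",
                       thresholdPercent = 10)
  expect_lt(sum(roiSizes(pTight)), sum(roiSizes(pFree)))
})

test_that("ReHo seed selection picks the most concordant voxel per ROI", {
  # plant a perfectly concordant neighborhood inside each of two blocks
  dim3 <- c(4, 2, 1)
  set.seed(20)
  series <- matrix(rnorm(30 * 8), 30)
  inc <- sort(rnorm(30))
  # voxel 1 (block A) and its neighbors 2, 5 share a monotone series;
  # voxel 4 (block B) with neighbors 3, 8 likewise
  series[, c(1, 2, 5)] <- inc
  series[, c(4, 3, 8)] <- rev(inc)
  vol <- volumeFromSeries(series, dim3)
  atlas <- Parcellation(array(c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L), dim3))
  seeds <- selectRehoSeeds(vol, atlas)
  expect_equal(unname(seeds[["1"]]), 1L)
  expect_equal(unname(seeds[["2"]]), 4L)
  # invariant to relabeling the atlas
  relab <- atlas@labels
  relab[] <- c(5L, 9L)[relab]
  seeds2 <- selectRehoSeeds(vol, Parcellation(relab))
  expect_equal(unname(sort(seeds2)), unname(sort(seeds)))
  # one ROI, one seed
  single <- Parcellation(array(1L, dim3))
  expect_length(selectRehoSeeds(vol, single), 1)
})

test_that("single-voxel ROI exclusion reports and removes the right ROIs", {
  lb <- array(0L, c(4, 1, 1))
  lb[] <- c(1L, 1L, 2L, 3L)
  res <- excludeSingleVoxelRois(Parcellation(lb))
  expect_equal(res$excludedCount, 2L)
  expect_equal(roiLabels(res$parcellation), 1L)
  expect_equal(res$parcellation@labels[3:4], c(0L, 0L))

  # identity on a parcellation with no singletons
  lb2 <- array(c(1L, 1L, 2L, 2L), c(4, 1, 1))
  res2 <- excludeSingleVoxelRois(Parcellation(lb2))
  expect_equal(res2$excludedCount, 0L)
  expect_identical(res2$parcellation@labels, lb2)

  # saturation: everything single-voxel
  lb3 <- array(1:4, c(4, 1, 1))
  res3 <- excludeSingleVoxelRois(Parcellation(lb3))
  expect_equal(res3$excludedCount, 4L)
  expect_length(roiLabels(res3$parcellation), 0)
})

test_that("static-parcellation filtering keeps the most consistent prefix", {
  # ROI 1: identical series (phi = 1); ROI 2: half-correlated; ROI 3: noise
  set.seed(44)
  a <- rnorm(40); b <- rnorm(40)
  C <- matrix(c(1, .5, .5, 1), 2)
  bc <- seriesWithCorrelation(C, 40, seed = 4)
  series <- cbind(a, a, a, a, a,
                  bc[, 1], bc[, 1], bc[, 2], bc[, 2], b,
                  matrix(rnorm(40 * 5), 40))
  vol <- volumeFromSeries(series, c(15, 1, 1))
  atlas <- Parcellation(array(rep(1:3, each = 5L), c(15, 1, 1)))
  f <- filterStaticParcellation(vol, atlas, voxelBudget = 10)
  expect_equal(roiLabels(f), c(1L, 2L))
  # unconstrained budget keeps everything
  f2 <- filterStaticParcellation(vol, atlas, voxelBudget = 15)
  expect_equal(roiLabels(f2), 1:3)
  # retained mean consistency is at least the atlas mean
  phis <- sapply(1:3, function(l) spatialConsistency(vol, roiVoxels(atlas, l)))
  expect_gte(mean(phis[1:2]), mean(phis))
  # budget below the smallest ROI: empty with warning
  expect_warning(f3 <- filterStaticParcellation(vol, atlas, 3), "budget")
  expect_length(roiLabels(f3), 0)
})

test_that("clustered parcellations beat shuffled-label controls on planted data", {
  cfg <- syntheticConfig(gridShape = c(8, 8, 2), nRois = 5,
                         nTimepoints = 80, nWindows = 1, noiseSeed = 17)
  ds <- generateReconfiguringDataset(cfg)
  vol <- ds$volume
  planted <- ds$parcellations[[1]]
  meanPhi <- function(p) {
    sz <- roiSizes(p)
    labs <- as.integer(names(sz)[sz >= 2])
    mean(sapply(labs, function(l) spatialConsistency(vol, roiVoxels(p, l))))
  }
  # label-shuffled control: same sizes, voxels scrambled across the mask
  set.seed(1)
  shuf <- planted@labels
  shuf[shuf > 0] <- sample(shuf[shuf > 0])
  ctrl <- meanPhi(Parcellation(shuf))
  seeds <- roiSeeds(planted)
  for (build in list(
    function() greedyGrow(vol, seeds, priority = "min_correlation"),
    function() greedyGrow(vol, seeds, priority = "weighted_mean_consistency"),
    function() craddockCluster(vol, targetClusters = 5))) {
    expect_gt(meanPhi(build()), ctrl)
  }
})
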