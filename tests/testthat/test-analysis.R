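test_that("stability scores reproduce the worked reorganization examples", {
  # 70% of voxels remain together, none gained: 0.7|I| / |I|
  expect_equal(stabilityScore(reorganizedNetwork(7, 0), 1, 1), 0.7)
  # all voxels kept, 30% newcomers: |I| / 1.3|I|
  expect_equal(stabilityScore(reorganizedNetwork(10, 3), 1, 1), 10 / 13)
  # 30% lost and 70% gained at once: 0.7|I| / (0.3 + 0.7 + 0.7)|I|
  expect_equal(stabilityScore(reorganizedNetwork(7, 7), 1, 1), 7 / 17)
})

test_that("stability score boundary behavior matches its definition", {
  net <- reorganizedNetwork(10, 0)         # unchanged ROI
  expect_equal(stabilityScore(net, 1, 1), 1)
  expect_error(stabilityScore(net, 2, 1), "last layer")
  # an ROI that disappears completely scores 0: layer-2 labels avoid all
  # voxels of layer-1 ROI 1
  dim3 <- c(30, 1, 1)
  lb1 <- array(0L, dim3); lb1[1:10] <- 1L; lb1[11:30] <- 2L
  lb2 <- array(0L, dim3); lb2[11:30] <- 2L
  set.seed(1)
  vol <- VoxelVolume(array(rnorm(30 * 20), c(dim3, 20)))
  net2 <- buildNetwork(vol, list(Parcellation(lb1), Parcellation(lb2)), 10)
  expect_equal(stabilityScore(net2, 1, 1), 0)
  # consistency with the trajectory's first offset
  tr <- trajectory(net, 1, 1)
  expect_equal(tr$value[tr$offset == 1], stabilityScore(net, 1, 1))
})

test_that("trajectories track disappearance and exact return", {
  dim3 <- c(12, 1, 1)
  ref <- 1:6
  lbA <- array(0L, dim3); lbA[ref] <- 1L; lbA[7:12] <- 2L
  lbB <- array(0L, dim3); lbB[1:3] <- 1L; lbB[4:12] <- 2L  # shattered
  set.seed(2)
  vol <- VoxelVolume(array(rnorm(12 * 30), c(dim3, 30)))
  net <- buildNetwork(vol, list(Parcellation(lbA), Parcellation(lbB),
                                Parcellation(lbA)), 10)
  tr <- trajectory(net, 1, 1)
  expect_equal(tr$offset, 1:2)
  expect_lt(tr$value[1], 1)            # disturbed at offset 1
  expect_equal(tr$value[2], 1)         # returns exactly as it was
  expect_true(all(tr$value >= 0 & tr$value <= 1))
  # static input: constant 1 trajectories
  netS <- buildNetwork(vol, replicate(3, Parcellation(lbA)), 10)
  expect_true(all(trajectory(netS, 1, 1)$value == 1))
  # minimum size filter and last-layer emptiness
  expect_error(trajectory(net, 1, 1, minSize = 7), "below minSize")
  expect_equal(nrow(trajectory(net, 3, 1)), 0)
})

test_that("pairwise stability is the mean of the two scores", {
  netA <- reorganizedNetwork(7, 0)      # ROI 1 scores 0.7
  s1 <- stabilityScore(netA, 1, 1)
  s2 <- stabilityScore(netA, 1, 2)
  expect_equal(pairwiseStability(netA, 1, 1, 2), (s1 + s2) / 2)
  expect_equal(pairwiseStability(netA, 1, 2, 1),
               pairwiseStability(netA, 1, 1, 2))   # symmetric
  # the paper-style worked pair: scores 0.7 and 0.41 average to 0.555
  expect_equal(mean(c(0.7, 0.41)), 0.555)
})

test_that("mean intralayer correlation averages a node's edge weights", {
  # exact correlations via an orthonormal construction; ROI series are
  # duplicated across two voxels each so no single-voxel ROIs appear
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.2
  C[1, 3] <- C[3, 1] <- 0.4
  C[1, 4] <- C[4, 1] <- 0.6
  C[2, 3] <- C[3, 2] <- 0.1
  C[2, 4] <- C[4, 2] <- 0.1
  C[3, 4] <- C[4, 3] <- 0.1
  s <- seriesWithCorrelation(C, 40, seed = 11)
  series <- s[, rep(1:4, each = 2)]
  series <- rbind(series, series)   # two windows with identical content
  vol <- volumeFromSeries(series, c(8, 1, 1))
  lb <- array(rep(1:4, each = 2L), c(8, 1, 1))
  net <- buildNetwork(vol, list(Parcellation(lb), Parcellation(lb)), 40)
  expect_equal(meanIntralayerCorrelation(net, 1, 1), mean(c(0.2, 0.4, 0.6)))
  expect_equal(intralayerWeights(net, 1)["1", "4"], 0.6)
})

test_that("binned curves use a closed first bin and half-open successors", {
  bc <- binnedCurve(c(0.05, 0.1, 0.1001, 1.0), c(1, 2, 3, 4))
  expect_equal(bc$count, c(2L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(bc$mean[1], 1.5)       # 0.05 and 0.1 share the first bin
  expect_equal(bc$mean[2], 3)         # 0.1001 spills into the second
  expect_equal(sum(bc$count), 4L)
  # constant y: every non-empty bin mean equals the constant
  x <- runif(100)
  bc2 <- binnedCurve(x, rep(7, 100))
  expect_true(all(bc2$mean[bc2$count > 0] == 7))
  expect_equal(sum(bc2$count), 100L)
  expect_error(binnedCurve(1:3 / 10, 1:2), "equal length")
})

test_that("empirical CDFs are sorted, normalized and step-like when static", {
  set.seed(5)
  vol <- VoxelVolume(array(rnorm(27 * 60), c(3, 3, 3, 60)))
  static <- generateRandomParcellation(vol@mask, 3, seed = 4)
  net <- buildNetwork(vol, replicate(3, static), 20)
  cdf <- interlayerWeightCdf(net, "weights")
  expect_true(all(cdf$value == 1))                # step at 1
  expect_equal(max(cdf$cdf), 1)
  cdfS <- interlayerWeightCdf(net, "stability")
  expect_true(all(cdfS$value == 1))
  # sort-and-rank oracle on a reconfiguring network
  cfg <- syntheticConfig(gridShape = c(5, 5, 1), nRois = 3,
                         nTimepoints = 60, nWindows = 3,
                         reconfigureFraction = 1, noiseSeed = 8)
  ds <- generateReconfiguringDataset(cfg)
  net2 <- buildNetwork(ds$volume, ds$parcellations, 20)
  cdf2 <- interlayerWeightCdf(net2, "weights")
  w <- sort(unlist(lapply(1:2, function(t) interlayerWeights(net2, t)$weight)))
  expect_equal(cdf2$value, w)
  expect_equal(cdf2$cdf, rank(w, ties.method = "first") / length(w))
  expect_true(all(diff(cdf2$cdf) >= 0))
})

test_that("consistency carryover is zero for identical window data", {
  set.seed(7)
  half <- matrix(rnorm(20 * 8), 20)
  series <- rbind(half, half)               # window 2 copies window 1
  vol <- volumeFromSeries(series, c(8, 1, 1))
  p <- Parcellation(array(rep(1:2, each = 4L), c(8, 1, 1)))
  w <- splitWindows(vol, 20)
  cc <- consistencyCarryover(vol, p, w[1, ], w[2, ])
  expect_equal(cc$perRoi$change, c(0, 0))
  expect_equal(cc$meanChange, 0)
  expect_error(consistencyCarryover(vol, p, list(start = 1, length = 20),
                                    list(start = 10, length = 20)),
               "overlap")
})

test_that("all-node stability pooling skips the last layer", {
  net <- reorganizedNetwork(7, 0)
  st <- stabilityScores(net)
  expect_equal(unique(st$layer), 1L)
  expect_equal(nrow(st), 2L)
  expect_equal(st$stability[st$label == 1], 0.7)
})
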