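# hand-built stacks with known puncta (no nuclei, no noise)
puncta <- function(centers, channels = "Cre", noiseSd = 0, seed = 2L) {
  p <- tinyParams(nNuclei = 0L, noiseSd = noiseSd, seed = seed)
  sp <- S4Vectors::DataFrame(channel = rep("Cre", nrow(centers)),
                             z_um = centers[, 1], y_um = centers[, 2],
                             x_um = centers[, 3],
                             owner = rep(NA_integer_, nrow(centers)))
  renderStack(generateNuclei(p), sp, p)
}

test_that("spot detection finds nothing in a blank channel", {
  sim <- puncta(matrix(numeric(0), 0, 3))
  expect_equal(nrow(detectSpots(sim$stack, "Cre",
                                spotConfig(threshold = 1000,
                                           thresholdIsQuantile = FALSE))),
               0L)
})

test_that("a single punctum is recovered with sub-voxel accuracy", {
  ctr <- matrix(c(6.23, 7.31, 6.84), 1)
  sim <- puncta(ctr)
  cfg <- spotConfig(threshold = 600, thresholdIsQuantile = FALSE)
  sp <- detectSpots(sim$stack, "Cre", cfg) # amplitude 3000 = 5x threshold
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$z_um - 6.23), 0.25) # half a z voxel
  expect_lt(abs(sp$y_um - 7.31), 0.05)
  expect_lt(abs(sp$x_um - 6.84), 0.05)
  expect_gte(sp$size_voxels, 2L)
  expect_equal(sp$peak, max(getChannel(sim$stack, "Cre")))
})

test_that("watershed separates two puncta merged into one cluster", {
  # centres 4 PSF z-sigmas apart: one supra-threshold cluster at a low
  # threshold, two intensity maxima
  ctr <- rbind(c(6.0, 7.0, 7.0), c(7.6, 7.0, 7.0))
  sim <- puncta(ctr) # background 500, peak 3500
  cfg <- spotConfig(threshold = 700, thresholdIsQuantile = FALSE,
                    watershedMinDepth = 300)
  vol <- getChannel(sim$stack, "Cre")
  lab <- labelObjects(vol > 700, voxel = voxelSize(sim$stack))
  expect_equal(max(lab), 1L) # really one cluster
  sp <- detectSpots(sim$stack, "Cre", cfg)
  expect_equal(nrow(sp), 2L)
  expect_equal(sort(round(sp$z_um, 1)), c(6.0, 7.6), tolerance = 0.1)
})

test_that("raising the threshold never increases the spot count", {
  set.seed(19)
  p <- tinyParams(nNuclei = 3L, seed = 23L)
  sim <- simulateStack(p)
  counts <- vapply(c(600, 900, 1500, 2500), function(thr)
    nrow(detectSpots(sim$stack, "Cre",
                     spotConfig(threshold = thr,
                                thresholdIsQuantile = FALSE))), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("watershed splitting repartitions but never changes the union", {
  p <- tinyParams(nNuclei = 3L, seed = 29L)
  sim <- simulateStack(p)
  vol <- getChannel(sim$stack, "Cre")
  thr <- 800
  cfg <- spotConfig(threshold = thr, thresholdIsQuantile = FALSE,
                    minSpotVoxels = 1L)
  sp <- detectSpots(sim$stack, "Cre", cfg)
  # with no size filter, fragment sizes partition the supra-threshold mask
  expect_equal(sum(sp$size_voxels), sum(vol > thr))
})

test_that("default-quantile detection recovers ground-truth counts exactly", {
  p <- tinyParams(nNuclei = 4L, seed = 37L)
  sim <- simulateStack(p)
  pc <- perCellCounts(sim$truth)
  sp <- trueSpots(sim$truth)
  for (ch in c("Cre", "Wt1")) {
    det <- detectSpots(sim$stack, ch)
    expect_equal(nrow(det), sum(sp$channel == ch))
  }
})

test_that("spot size histogram is an exact, conserving tally", {
  expect_equal(nrow(spotSizeHistogram(
    S4Vectors::DataFrame(size_voxels = integer()))), 0L)
  h <- spotSizeHistogram(S4Vectors::DataFrame(size_voxels = c(4L, 4L, 7L)))
  expect_equal(as.data.frame(h),
               data.frame(size_voxels = c(4L, 7L), count = c(2L, 1L)))
  set.seed(5)
  sizes <- sample(2:20, 57, replace = TRUE)
  h2 <- spotSizeHistogram(S4Vectors::DataFrame(size_voxels = sizes))
  expect_equal(sum(h2$count), 57L)
})
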