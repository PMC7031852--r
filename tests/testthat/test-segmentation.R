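vox <- c(0.5, 0.1, 0.1)

test_that("Gaussian smoothing preserves constants, peaks and the mean", {
  const <- array(7.5, c(6, 10, 10))
  sm <- smoothVolume(const, 0.3, vox)
  expect_equal(sm, const, tolerance = 1e-12)

  v <- array(0, c(9, 21, 21))
  v[5, 11, 11] <- 100
  sm <- smoothVolume(v, c(0.5, 0.3, 0.3), vox)
  expect_equal(as.integer(arrayInd(which.max(sm), dim(sm))), c(5L, 11L, 11L))
  expect_lt(max(sm), 100)

  set.seed(42)
  r <- array(rnorm(9 * 21 * 21, 50, 10), c(9, 21, 21))
  sm <- smoothVolume(r, c(0.6, 0.25, 0.25), vox)
  expect_lt(abs(mean(sm) - mean(r)) / mean(r), 0.001)

  expect_error(smoothVolume(r, -1, vox), "positive")
})

test_that("smoothing matches direct truncated-kernel convolution", {
  set.seed(7)
  v <- array(runif(11^3, 0, 100), c(11, 11, 11))
  isoVox <- c(1, 1, 1)
  sm <- smoothVolume(v, c(2, 2, 2), isoVox) # sigma = 2 voxels
  oracle <- bruteGaussSmooth(v, c(2, 2, 2))
  expect_lt(max(abs(sm - oracle) / (abs(oracle) + 1e-12)), 1e-6)
})

test_that("adaptive threshold follows the local mean + offset contract", {
  cfg <- segmentationConfig(adaptWindow = 2, adaptOffset = 5,
                            offsetIsFraction = FALSE)
  const <- array(3, c(8, 16, 16))
  expect_true(all(!adaptiveThreshold(const, cfg, vox)))

  # identical to a brute-force sliding-window mean on a random 16^3 grid
  set.seed(11)
  v <- array(runif(16^3, 0, 100), c(16, 16, 16))
  isoVox <- c(1, 1, 1)
  cfg2 <- segmentationConfig(adaptWindow = 5, adaptOffset = 2,
                             offsetIsFraction = FALSE)
  got <- adaptiveThreshold(v, cfg2, isoVox)
  lm <- bruteLocalMean(v, c(2L, 2L, 2L))
  expect_identical(got, v > lm + 2)

  # a bright blob on zero background is recovered (offset 0)
  blob <- array(0, c(16, 16, 16))
  blob[6:10, 6:10, 6:10] <- 10
  cfg3 <- segmentationConfig(adaptWindow = 7, adaptOffset = 0.01,
                             offsetIsFraction = FALSE)
  m <- adaptiveThreshold(blob, cfg3, isoVox)
  expect_true(all(m[7:9, 7:9, 7:9]))

  expect_error(adaptiveThreshold(v, segmentationConfig(adaptWindow = 0.2),
                                 vox), "fewer than 3 voxels")
})

test_that("raising the adaptive offset never grows the foreground", {
  set.seed(3)
  v <- array(runif(10 * 20 * 20, 0, 50), c(10, 20, 20))
  offs <- c(0, 2, 5, 12)
  masks <- lapply(offs, function(o)
    adaptiveThreshold(v, segmentationConfig(adaptWindow = 4, adaptOffset = o,
                                            offsetIsFraction = FALSE),
                      c(1, 1, 1)))
  for (i in seq_len(length(offs) - 1L))
    expect_true(all(masks[[i]] | !masks[[i + 1L]])) # superset relation
})

test_that("connected-component labelling matches a flood-fill oracle", {
  expect_equal(max(labelObjects(array(FALSE, c(5, 5, 5)))), 0L)

  m <- array(FALSE, c(8, 12, 12))
  m[2:4, 2:4, 2:4] <- TRUE
  m[5:7, 8:11, 8:11] <- TRUE
  expect_equal(max(labelObjects(m, voxel = c(1, 1, 1))), 2L)

  set.seed(21)
  for (rep in 1:4) {
    r <- array(runif(12^3) < 0.25, c(12, 12, 12))
    got <- labelObjects(r, voxel = c(1, 1, 1))
    oracle <- bruteFloodFill(r)
    expect_true(sameUpToRelabel(got, oracle))
  }
})

test_that("labelling drops objects below the minimum volume", {
  m <- array(FALSE, c(8, 12, 12))
  m[2:4, 2:4, 2:4] <- TRUE       # 27 voxels
  m[6, 10, 10] <- TRUE           # 1 voxel
  lab <- labelObjects(m, minVolume = 5, voxel = c(1, 1, 1))
  expect_equal(max(lab), 1L)
  expect_equal(sum(lab > 0), 27L)
})

test_that("watershed splitting separates fused spheres, keeps compact ones", {
  isoVox <- c(0.5, 0.5, 0.5)
  mk <- function(centers, r) {
    d <- c(24L, 48L, 24L)
    a <- array(FALSE, d)
    for (x in 1:d[3]) for (y in 1:d[2]) for (z in 1:d[1]) {
      p <- (c(z, y, x) - 0.5) * isoVox
      for (k in seq_len(nrow(centers)))
        if (sum((p - centers[k, ])^2) <= r^2) a[z, y, x] <- TRUE
    }
    a
  }
  cfg <- segmentationConfig(maxVolume = 40, seedMinSep = 2.5,
                            seedMinHeight = 1)
  # two equal spheres fused at a thin neck
  ctrs <- rbind(c(6, 9, 6), c(6, 15.4, 6)) # r = 3.3 -> centres 6.4 apart
  fused <- mk(ctrs, 3.3)
  lab <- labelObjects(fused, voxel = isoVox)
  expect_equal(max(lab), 1L) # really fused
  split <- splitOversized(lab, cfg, isoVox)
  expect_equal(max(split), 2L)
  st <- as.data.frame(nuclei(new("NucleusSet", labels = split,
                                 table = smFISHcoloc:::labelStats(split, isoVox),
                                 voxelSize = isoVox)))
  for (k in 1:2) {
    dd <- sqrt((st$centroid_z_um - ctrs[k, 1])^2 +
               (st$centroid_y_um - ctrs[k, 2])^2 +
               (st$centroid_x_um - ctrs[k, 3])^2)
    expect_lt(min(dd), 0.5) # within one (isotropic) voxel of the centre
  }
  # splitting preserves the foreground voxel set exactly
  expect_identical(split > 0L, lab > 0L)

  # single compact sphere above maxVolume stays one object
  single <- mk(matrix(c(6, 9, 6), 1), 3.3)
  lab1 <- labelObjects(single, voxel = isoVox)
  expect_equal(max(splitOversized(lab1, cfg, isoVox)), 1L)

  # all objects below maxVolume pass through untouched
  cfgBig <- segmentationConfig(maxVolume = 1000)
  expect_identical(splitOversized(lab, cfgBig, isoVox), lab)
})

test_that("full nucleus segmentation recovers well-separated nuclei", {
  blank <- ImageStack(list(DAPI = array(500, c(16, 60, 60))), vox)
  expect_equal(nrow(nuclei(segmentNuclei(blank))), 0L)

  p <- synthParams(nNuclei = 20L, gridShape = c(32L, 240L, 240L),
                   touchingFraction = 0, seed = 31L)
  sim <- simulateStack(p)
  ns <- segmentNuclei(sim$stack)
  tb <- nuclei(ns)
  nt <- trueNuclei(sim$truth)
  expect_equal(nrow(tb), 20L)
  for (i in seq_len(nrow(nt))) {
    dd <- sqrt((tb$centroid_z_um - nt$centroid_z_um[i])^2 +
               (tb$centroid_y_um - nt$centroid_y_um[i])^2 +
               (tb$centroid_x_um - nt$centroid_x_um[i])^2)
    expect_lt(min(dd), 1) # centroid within 1 um of truth
  }
  expect_error(segmentNuclei(sim$stack, "nope"), "DAPI")
})

test_that("a touching pair fused above maxVolume is split into two", {
  p <- synthParams(nNuclei = 2L, gridShape = c(32L, 160L, 160L),
                   touchingFraction = 0.5, seed = 13L)
  sim <- simulateStack(p)
  nt <- trueNuclei(sim$truth)
  # construction check: the two nuclei really touch
  dv <- c(nt$centroid_z_um[2] - nt$centroid_z_um[1],
          nt$centroid_y_um[2] - nt$centroid_y_um[1],
          nt$centroid_x_um[2] - nt$centroid_x_um[1])
  expect_lt(sqrt(sum(dv^2)), 2 * 2.5 + 0.3)
  ns <- segmentNuclei(sim$stack)
  expect_equal(nrow(nuclei(ns)), 2L)
})
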