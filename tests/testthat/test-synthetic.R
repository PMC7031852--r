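test_that("nucleus generation is empty at n = 0 and seed-deterministic", {
  p <- tinyParams(nNuclei = 0L)
  expect_equal(nrow(generateNuclei(p)), 0L)
  p2 <- tinyParams(nNuclei = 4L, seed = 9L)
  a <- generateNuclei(p2)
  b <- generateNuclei(p2)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("requested touching pairs really touch (brute-force gap check)", {
  p <- synthParams(seed = 5L) # default: 50 nuclei, touchingFraction 0.2
  nt <- generateNuclei(p)
  expect_equal(nrow(nt), 50L)
  ctr <- cbind(nt$centroid_z_um, nt$centroid_y_um, nt$centroid_x_um)
  sa <- cbind(nt$semi_z_um, nt$semi_y_um, nt$semi_x_um)
  # independent pairwise surface-gap computation over all pairs
  gap <- function(i, j) {
    dv <- ctr[j, ] - ctr[i, ]
    dd <- sqrt(sum(dv^2))
    u <- dv / dd
    dd - 1 / sqrt(sum(u^2 / sa[i, ]^2)) - 1 / sqrt(sum(u^2 / sa[j, ]^2))
  }
  oneVoxel <- max(p@voxelSize)
  touching <- 0L
  for (i in 1:49) for (j in (i + 1):50)
    if (gap(i, j) <= oneVoxel) touching <- touching + 1L
  expect_gte(touching, 10L * 0.2 * 50 / 10) # >= 10 contacts for 10 flagged
  # placed nuclei stay inside the grid
  extent <- p@gridShape * p@voxelSize
  expect_true(all(ctr > 0) && all(t(t(ctr) - extent) < 0))
})

test_that("spot placement respects counts, containment and margins", {
  p0 <- tinyParams(nNuclei = 2L,
                   spotsPerCell = list(Cre = c(0L, 0L), Wt1 = c(0L, 0L)),
                   extranuclearRate = 0)
  nt0 <- generateNuclei(p0)
  expect_equal(nrow(placeSpots(nt0, p0)), 0L)

  p1 <- tinyParams(nNuclei = 1L, channels = "Cre",
                   spotsPerCell = list(Cre = c(3L, 3L)),
                   extranuclearRate = 0, seed = 4L)
  nt1 <- generateNuclei(p1)
  sp1 <- placeSpots(nt1, p1)
  expect_equal(nrow(sp1), 3L)
  for (i in 1:3) {
    q <- sum(((c(sp1$z_um[i], sp1$y_um[i], sp1$x_um[i]) -
                 c(nt1$centroid_z_um, nt1$centroid_y_um,
                   nt1$centroid_x_um)) /
                c(nt1$semi_z_um, nt1$semi_y_um, nt1$semi_x_um))^2)
    expect_lt(q, 1) # strictly inside the ellipsoid
  }

  # extranuclear-only: every spot unowned and outside every ellipsoid
  p2 <- tinyParams(nNuclei = 3L,
                   spotsPerCell = list(Cre = c(0L, 0L), Wt1 = c(0L, 0L)),
                   extranuclearRate = 20, seed = 6L)
  nt2 <- generateNuclei(p2)
  sp2 <- placeSpots(nt2, p2)
  expect_gt(nrow(sp2), 0L)
  expect_true(all(is.na(sp2$owner)))
  for (i in seq_len(nrow(sp2))) {
    for (j in seq_len(nrow(nt2))) {
      q <- sum(((c(sp2$z_um[i], sp2$y_um[i], sp2$x_um[i]) -
                   c(nt2$centroid_z_um[j], nt2$centroid_y_um[j],
                     nt2$centroid_x_um[j])) /
                  c(nt2$semi_z_um[j], nt2$semi_y_um[j],
                    nt2$semi_x_um[j]))^2)
      expect_gt(q, 1)
    }
  }
})

test_that("spot conservation: totals equal per-cell tallies plus free spots", {
  p <- tinyParams(nNuclei = 4L, seed = 8L)
  nt <- generateNuclei(p)
  sp <- placeSpots(nt, p)
  sim <- renderStack(nt, sp, p)
  pc <- perCellCounts(sim$truth)
  expect_equal(nrow(sp), sum(pc) + sum(is.na(sp$owner)))
  # every owned spot lies inside its owner ellipsoid
  owned <- sp[!is.na(sp$owner), ]
  for (i in seq_len(nrow(owned))) {
    j <- match(owned$owner[i], nt$label)
    q <- sum(((c(owned$z_um[i], owned$y_um[i], owned$x_um[i]) -
                 c(nt$centroid_z_um[j], nt$centroid_y_um[j],
                   nt$centroid_x_um[j])) /
                c(nt$semi_z_um[j], nt$semi_y_um[j], nt$semi_x_um[j]))^2)
    expect_lte(q, 1)
  }
})

test_that("rendering: flat background, punctum peak location, determinism", {
  pz <- tinyParams(nNuclei = 0L, noiseSd = 0)
  empty <- S4Vectors::DataFrame(channel = character(), z_um = numeric(),
                                y_um = numeric(), x_um = numeric(),
                                owner = integer())
  sim0 <- renderStack(generateNuclei(pz), empty, pz)
  for (ch in channelNames(sim0$stack))
    expect_true(all(getChannel(sim0$stack, ch) == pz@backgroundLevel))

  sp <- S4Vectors::DataFrame(channel = "Cre", z_um = 6.23, y_um = 7.31,
                             x_um = 7.14, owner = NA_integer_)
  sim1 <- renderStack(generateNuclei(pz), sp, pz)
  cre <- getChannel(sim1$stack, "Cre")
  peakIdx <- arrayInd(which.max(cre), dim(cre))
  nearest <- floor(c(6.23, 7.31, 7.14) / pz@voxelSize) + 1L
  expect_equal(as.integer(peakIdx), as.integer(nearest))

  p <- tinyParams(nNuclei = 3L, seed = 12L)
  s1 <- simulateStack(p)
  s2 <- simulateStack(p)
  for (ch in channelNames(s1$stack))
    expect_identical(getChannel(s1$stack, ch), getChannel(s2$stack, ch))
  expect_identical(as.data.frame(trueSpots(s1$truth)),
                   as.data.frame(trueSpots(s2$truth)))
})

test_that("rendering validates grid/voxel consistency", {
  p <- tinyParams(nNuclei = 2L, seed = 3L)
  nt <- generateNuclei(p)
  sp <- placeSpots(nt, p)
  shrunk <- tinyParams(nNuclei = 2L, seed = 3L)
  shrunk@gridShape <- c(8L, 40L, 40L) # nuclei now out of range
  expect_error(renderStack(nt, sp, shrunk), "mismatch")
})
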