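# a hand-built segmentation: one labelled box per nucleus
boxNuclei <- function() {
  lab <- array(0L, c(10, 30, 30))
  lab[3:7, 4:12, 4:12] <- 1L
  lab[3:7, 18:26, 18:26] <- 2L
  new("NucleusSet", labels = lab,
      table = smFISHcoloc:::labelStats(lab, c(0.5, 0.1, 0.1)),
      voxelSize = c(0.5, 0.1, 0.1))
}

spotsAt <- function(coords, channel = "Cre") {
  S4Vectors::DataFrame(channel = rep(channel, nrow(coords)),
                       z_um = coords[, 1], y_um = coords[, 2],
                       x_um = coords[, 3],
                       size_voxels = rep(3L, nrow(coords)),
                       peak = rep(1000, nrow(coords)),
                       status = rep("unassigned", nrow(coords)),
                       nucleus = rep(NA_integer_, nrow(coords)))
}

test_that("spots are assigned by the label of their centroid voxel", {
  ns <- boxNuclei()
  tb <- as.data.frame(nuclei(ns))
  atCentroid <- spotsAt(cbind(tb$centroid_z_um[1], tb$centroid_y_um[1],
                              tb$centroid_x_um[1]))
  a <- assignSpots(atCentroid, ns)
  expect_equal(a$status, "assigned")
  expect_equal(a$nucleus, 1L)

  inBackground <- spotsAt(matrix(c(0.6, 0.3, 0.3), 1))
  b <- assignSpots(inBackground, ns)
  expect_equal(b$status, "excluded")
  expect_true(is.na(b$nucleus))

  # conservation on a random mixture
  set.seed(77)
  mix <- spotsAt(cbind(runif(40, 0, 5), runif(40, 0, 3), runif(40, 0, 3)))
  m <- assignSpots(mix, ns)
  expect_equal(sum(m$status == "assigned") + sum(m$status == "excluded"),
               40L)
})

test_that("per-cell profiles tally assigned spots and keep zero cells", {
  ns <- boxNuclei()
  tb <- as.data.frame(nuclei(ns))
  none <- spotsAt(matrix(numeric(0), 0, 3))
  se0 <- cellCounts(none, ns, c("Cre", "Wt1"))
  expect_equal(dim(se0), c(2L, 2L))
  expect_true(all(SummarizedExperiment::assay(se0, "counts") == 0L))

  three <- assignSpots(
    spotsAt(cbind(rep(tb$centroid_z_um[1], 3), rep(tb$centroid_y_um[1], 3),
                  rep(tb$centroid_x_um[1], 3))), ns)
  se <- cellCounts(three, ns, c("Cre", "Wt1"))
  cnt <- SummarizedExperiment::assay(se, "counts")
  expect_equal(unname(cnt["1", "Cre"]), 3L)
  expect_equal(unname(cnt["2", "Cre"]), 0L)

  bad <- three
  bad$nucleus <- rep(99L, 3)
  expect_error(cellCounts(bad, ns, c("Cre", "Wt1")), "unknown nucleus")
})

test_that("per-cell counts equal ground truth on an isolated-spot fixture", {
  p <- tinyParams(nNuclei = 4L, touchingFraction = 0, seed = 41L)
  sim <- simulateStack(p)
  ns <- segmentNuclei(sim$stack)
  sp <- do.call(rbind, lapply(c("Cre", "Wt1"), function(ch)
    assignSpots(detectSpots(sim$stack, ch), ns)))
  pr <- cellCounts(sp, ns, c("Cre", "Wt1"))
  ev <- evaluateRecovery(sim$truth, ns, pr)
  expect_equal(ev$n_detected, 4L)
  expect_equal(ev$count_exact_pct, 100)
})

test_that("positivity: a cell needs more than k transcripts", {
  m <- matrix(0:5, 6, 1, dimnames = list(1:6, "Cre"))
  se <- SummarizedExperiment::SummarizedExperiment(list(counts = m))
  pos <- SummarizedExperiment::assay(callPositive(se, k = 2), "positive")
  expect_equal(unname(pos[, 1]), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  # monotone in count, antitone in k
  for (k in 0:4) {
    pk <- SummarizedExperiment::assay(callPositive(se, k), "positive")[, 1]
    expect_true(all(diff(pk) >= 0))
    if (k > 0) {
      prev <- SummarizedExperiment::assay(callPositive(se, k - 1),
                                          "positive")[, 1]
      expect_true(all(prev | !pk))
    }
  }
  expect_error(callPositive(se, -1), "nonnegative")
})

test_that("coexpression restricts target counts to reporter-positive cells", {
  m <- matrix(c(3L, 2L, 4L, 5L, 9L, 0L), 3, 2,
              dimnames = list(1:3, c("Cre", "Wt1")))
  se <- callPositive(
    SummarizedExperiment::SummarizedExperiment(list(counts = m)), 2)
  expect_equal(coexpressionCounts(se, "Cre", "Wt1"), c(5L, 0L))
  pos <- SummarizedExperiment::assay(se, "positive")[, "Cre"]
  expect_length(coexpressionCounts(se, "Cre", "Wt1"), sum(pos))

  none <- callPositive(SummarizedExperiment::SummarizedExperiment(
    list(counts = matrix(c(0L, 1L), 2, 1,
                         dimnames = list(1:2, "Cre")))), 2)
  expect_length(coexpressionCounts(none, "Cre", "Cre"), 0L)
  expect_error(coexpressionCounts(se, "Gfp", "Wt1"), "Gfp")
})

test_that("group comparison is a pooled-variance Student t test", {
  same <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  r <- compareGroups(c(1, 2), c(3, 4))
  expect_equal(r$t, -2.828, tolerance = 5e-4) # = -2 / sqrt(1/2)
  expect_equal(r$df, 2)
  rs <- compareGroups(c(3, 4), c(1, 2))
  expect_equal(rs$t, -r$t)
  expect_equal(rs$p, r$p)

  # oracle: the pooled-variance formula written out by hand
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(7, 5, 2); b <- rnorm(9, 6, 2)
    sp2 <- (6 * var(a) + 8 * var(b)) / 14
    tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 7 + 1 / 9))
    pHand <- 2 * pt(-abs(tHand), 14)
    got <- compareGroups(a, b)
    expect_equal(got$t, tHand, tolerance = 1e-12)
    expect_equal(got$p, pHand, tolerance = 1e-12)
    expect_equal(got$df, 14)
  }

  expect_error(compareGroups(1, c(2, 3)), "at least 2")
  expect_error(compareGroups(c(2, 2), c(2, 2)), "variance")
  welch <- compareGroups(c(1, 2, 3), c(2, 4, 9, 16), varEqual = FALSE)
  expect_lt(welch$df, 5) # Welch df is fractional and smaller
})
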