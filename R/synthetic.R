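#' Generate ground-truth nuclei for a synthetic stack
#'
#' Places \code{nNuclei} axis-aligned ellipsoids (semi-axes drawn
#' independently from \code{radiusRange}, so no two are identical) fully
#' inside the grid by rejection sampling. A \code{touchingFraction} subset
#' is placed so its surface lies within one voxel of a neighbour's surface
#' (surface gap drawn from 0.02-0.25 um), to exercise the splitting stage;
#' the remainder keep a surface gap of at least 1 um from every other
#' nucleus. Surface gaps between ellipsoids are measured along the
#' centre-to-centre direction (exact for spheres, tight for the
#' near-spherical default shapes).
#'
#' @param params a \linkS4class{SynthParams}.
#' @param seed optional integer overriding the seed derived from
#'   \code{params@seed}.
#' @param maxAttempts rejection-sampling attempts per nucleus before
#'   giving up.
#' @return \code{DataFrame} with columns \code{label},
#'   \code{centroid_z_um}, \code{centroid_y_um}, \code{centroid_x_um},
#'   \code{semi_z_um}, \code{semi_y_um}, \code{semi_x_um},
#'   \code{touching}.
#' @examples
#' p <- synthParams(nNuclei = 4L, gridShape = c(24L, 150L, 150L), seed = 7L)
#' generateNuclei(p)
#' @export
generateNuclei <- function(params, seed = NULL, maxAttempts = 5000L) {
  stopifnot(is(params, "SynthParams"))
  validObject(params)
  if (is.null(seed)) seed <- childSeeds(params@seed, 4L)[1L]
  n <- params@nNuclei
  empty <- S4Vectors::DataFrame(label = integer(), centroid_z_um = numeric(),
                                centroid_y_um = numeric(),
                                centroid_x_um = numeric(),
                                semi_z_um = numeric(), semi_y_um = numeric(),
                                semi_x_um = numeric(), touching = logical())
  if (n == 0L) return(empty)
  extent <- params@gridShape * params@voxelSize
  nTouch <- round(params@touchingFraction * n)
  touchFlag <- c(rep(FALSE, n - nTouch), rep(TRUE, nTouch))

  # surface gap along the centre line: ||c2-c1|| - r1(u) - r2(u),
  # with r(u) = 1/sqrt(sum(u_i^2 / a_i^2)) the directional radius
  dirRadius <- function(a, u) 1 / sqrt(sum(u * u / (a * a)))
  surfaceGap <- function(c1, a1, c2, a2) {
    d <- sqrt(sum((c2 - c1)^2))
    if (d == 0) return(-Inf)
    u <- (c2 - c1) / d
    d - dirRadius(a1, u) - dirRadius(a2, u)
  }

  withSeed(seed, {
    centers <- matrix(NA_real_, n, 3L)
    semis <- matrix(NA_real_, n, 3L)
    for (i in seq_len(n)) {
      a <- runif(3L, params@radiusRange[1L], params@radiusRange[2L])
      if (any(extent < 2 * a))
        stop("grid extent ", paste(signif(extent, 4), collapse = " x "),
             " um too small for nuclei of semi-axes up to ",
             params@radiusRange[2L], " um")
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        if (touchFlag[i] && i > 1L) {
          partner <- sample.int(i - 1L, 1L)
          u <- rnorm(3L)
          u <- u / sqrt(sum(u * u))
          gap <- runif(1L, 0.02, 0.25)
          d <- dirRadius(semis[partner, ], u) + dirRadius(a, u) + gap
          ctr <- centers[partner, ] + u * d
        } else {
          ctr <- runif(3L, a, extent - a)
        }
        if (any(ctr < a) || any(ctr > extent - a)) next
        ok <- TRUE
        if (i > 1L) {
          for (j in seq_len(i - 1L)) {
            g <- surfaceGap(ctr, a, centers[j, ], semis[j, ])
            lim <- if (touchFlag[i]) 0.02 else 1.0
            if (touchFlag[i] && j == partner) lim <- 0.0
            if (g < lim) { ok <- FALSE; break }
          }
        }
        if (ok) {
          centers[i, ] <- ctr
          semis[i, ] <- a
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("failed to place nucleus ", i, " after ", maxAttempts,
             " attempts: reduce nNuclei, radiusRange or touchingFraction, ",
             "or enlarge gridShape")
    }
    S4Vectors::DataFrame(label = seq_len(n), centroid_z_um = centers[, 1L],
                         centroid_y_um = centers[, 2L],
                         centroid_x_um = centers[, 3L],
                         semi_z_um = semis[, 1L], semi_y_um = semis[, 2L],
                         semi_x_um = semis[, 3L], touching = touchFlag)
  })
}

# point-in-ellipsoid helper (shared with tests via the exported geometry)
insideEllipsoid <- function(p, ctr, semi, shrink = 0) {
  sum(((p - ctr) / (semi - shrink))^2) <= 1
}

#' Place ground-truth transcript spots
#'
#' For each nucleus and channel an intended transcript count is drawn
#' uniformly from \code{spotsPerCell} and that many centroids are placed
#' uniformly inside the ellipsoid shrunk by \code{innerMargin}. Free
#' (extranuclear) spots are added per channel with Poisson count
#' \code{extranuclearRate} per 1000 um^3 of grid volume, outside every
#' nucleus expanded by \code{outerMargin}. Spots of one channel keep a
#' mutual distance of at least \code{minSpotSep} so puncta are resolvable.
#'
#' @param nucleiTruth output of \code{\link{generateNuclei}} (may be empty).
#' @param params a \linkS4class{SynthParams}.
#' @param seed optional integer overriding the derived stage seed.
#' @param maxAttempts rejection attempts per spot.
#' @return \code{DataFrame} with columns \code{channel}, \code{z_um},
#'   \code{y_um}, \code{x_um}, \code{owner} (nucleus label, \code{NA} for
#'   free spots).
#' @examples
#' p <- synthParams(nNuclei = 2L, gridShape = c(24L, 150L, 150L), seed = 7L)
#' nt <- generateNuclei(p)
#' sp <- placeSpots(nt, p)
#' table(sp$channel, useNA = "ifany")
#' @export
placeSpots <- function(nucleiTruth, params, seed = NULL,
                       maxAttempts = 2000L) {
  stopifnot(is(params, "SynthParams"))
  if (is.null(seed)) seed <- childSeeds(params@seed, 4L)[2L]
  extent <- params@gridShape * params@voxelSize
  gridVol <- prod(extent)
  nNuc <- nrow(nucleiTruth)
  ctrs <- if (nNuc) cbind(nucleiTruth$centroid_z_um,
                          nucleiTruth$centroid_y_um,
                          nucleiTruth$centroid_x_um) else
    matrix(0, 0L, 3L)
  semis <- if (nNuc) cbind(nucleiTruth$semi_z_um, nucleiTruth$semi_y_um,
                           nucleiTruth$semi_x_um) else matrix(0, 0L, 3L)
  labs <- if (nNuc) nucleiTruth$label else integer()

  withSeed(seed, {
    chn <- character()
    pos <- matrix(NA_real_, 0L, 3L)
    owner <- integer()
    for (ch in params@channels) {
      placedCh <- matrix(NA_real_, 0L, 3L)
      rng <- params@spotsPerCell[[ch]]
      for (i in seq_len(nNuc)) {
        cnt <- if (rng[1L] == rng[2L]) rng[1L] else
          sample(seq.int(rng[1L], rng[2L]), 1L)
        a <- semis[i, ] - params@innerMargin
        if (cnt > 0L && any(a <= 0))
          stop("innerMargin leaves no interior in nucleus ", i)
        for (k in seq_len(cnt)) {
          done <- FALSE
          for (att in seq_len(maxAttempts)) {
            u <- rnorm(3L)
            u <- u / sqrt(sum(u * u)) * runif(1L)^(1 / 3)
            p <- ctrs[i, ] + u * a
            if (nrow(placedCh) &&
                min(colSums((t(placedCh) - p)^2)) < params@minSpotSep^2)
              next
            placedCh <- rbind(placedCh, p)
            chn <- c(chn, ch)
            pos <- rbind(pos, p)
            owner <- c(owner, labs[i])
            done <- TRUE
            break
          }
          if (!done)
            stop("failed to place a '", ch, "' spot in nucleus ", i,
                 ": lower spotsPerCell or minSpotSep")
        }
      }
      nFree <- rpois(1L, params@extranuclearRate * gridVol / 1000)
      border <- 0.5
      for (k in seq_len(nFree)) {
        done <- FALSE
        for (att in seq_len(maxAttempts)) {
          p <- runif(3L, border, extent - border)
          inNuc <- FALSE
          for (i in seq_len(nNuc)) {
            if (insideEllipsoid(p, ctrs[i, ], semis[i, ],
                                shrink = -params@outerMargin)) {
              inNuc <- TRUE
              break
            }
          }
          if (inNuc) next
          if (nrow(placedCh) &&
              min(colSums((t(placedCh) - p)^2)) < params@minSpotSep^2)
            next
          placedCh <- rbind(placedCh, p)
          chn <- c(chn, ch)
          pos <- rbind(pos, p)
          owner <- c(owner, NA_integer_)
          done <- TRUE
          break
        }
        if (!done)
          stop("failed to place a free '", ch, "' spot: grid too crowded ",
               "(extranuclearRate/outerMargin)")
      }
    }
    S4Vectors::DataFrame(channel = chn, z_um = pos[, 1L], y_um = pos[, 2L],
                         x_um = pos[, 3L], owner = owner)
  })
}

# tally of owned spots by (nucleus, channel)
perCellTally <- function(nucleiTruth, spotsTruth, channels) {
  m <- matrix(0L, nrow(nucleiTruth), length(channels),
              dimnames = list(as.character(nucleiTruth$label), channels))
  if (nrow(spotsTruth)) {
    owned <- spotsTruth[!is.na(spotsTruth$owner), , drop = FALSE]
    if (nrow(owned)) {
      t2 <- table(factor(owned$owner, levels = nucleiTruth$label),
                  factor(owned$channel, levels = channels))
      m[] <- as.integer(t2)
    }
  }
  m
}

#' Render a synthetic multi-channel stack
#'
#' The DAPI channel is the sum of the binary ellipsoid masks blurred by the
#' PSF and scaled to \code{dapiAmplitude}; each probe channel is the sum of
#' anisotropic Gaussian puncta of peak \code{spotAmplitude} at the true
#' spot centroids. All channels receive the constant background, seeded
#' Gaussian read noise (and optional Poisson shot noise), and are clipped
#' to \code{[0, clipMax]} and rounded to integer grey levels.
#'
#' @param nucleiTruth output of \code{\link{generateNuclei}}.
#' @param spotsTruth output of \code{\link{placeSpots}}.
#' @param params a \linkS4class{SynthParams}.
#' @param seed optional integer overriding the derived stage seed.
#' @return list with elements \code{stack} (an \linkS4class{ImageStack}
#'   with channels \code{DAPI} plus the probe channels) and \code{truth}
#'   (a \linkS4class{GroundTruth}).
#' @examples
#' p <- synthParams(nNuclei = 2L, gridShape = c(24L, 150L, 150L), seed = 7L)
#' sim <- renderStack(generateNuclei(p), placeSpots(generateNuclei(p), p), p)
#' sim$stack
#' @export
renderStack <- function(nucleiTruth, spotsTruth, params, seed = NULL) {
  stopifnot(is(params, "SynthParams"))
  if (is.null(seed)) seed <- childSeeds(params@seed, 4L)[3L]
  dims <- params@gridShape
  voxel <- params@voxelSize
  extent <- dims * voxel
  if (nrow(nucleiTruth)) {
    ctr <- cbind(nucleiTruth$centroid_z_um, nucleiTruth$centroid_y_um,
                 nucleiTruth$centroid_x_um)
    if (any(ctr < 0) || any(t(t(ctr) - extent) > 0))
      stop("nucleus centroids fall outside the grid: grid/voxel mismatch ",
           "between generation and rendering parameters")
  }
  if (nrow(spotsTruth)) {
    sp <- cbind(spotsTruth$z_um, spotsTruth$y_um, spotsTruth$x_um)
    if (any(sp < 0) || any(t(t(sp) - extent) > 0))
      stop("spot centroids fall outside the grid: grid/voxel mismatch ",
           "between generation and rendering parameters")
  }
  nCh <- length(params@channels) + 1L
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, nCh + 1L))
  finish <- function(img, sd, noiseSeed) {
    if (!params@shotNoise)
      return(array(cpp_finish_channel(img, params@backgroundLevel, sd,
                                      as.double(noiseSeed),
                                      params@clipMax), dims))
    img <- img + params@backgroundLevel
    if (sd > 0)
      img <- img + cpp_gauss_noise(length(img), sd, as.double(noiseSeed))
    img <- withSeed(noiseSeed + 1L,
                    rpois(length(img), lambda = pmax(img, 0)))
    img <- round(pmin(pmax(img, 0), params@clipMax))
    array(img, dims)
  }
  chans <- vector("list", nCh)
  names(chans) <- c("DAPI", params@channels)
  if (nrow(nucleiTruth)) {
    mask <- cpp_fill_ellipsoids(dims,
      cbind(nucleiTruth$centroid_z_um, nucleiTruth$centroid_y_um,
            nucleiTruth$centroid_x_um),
      cbind(nucleiTruth$semi_z_um, nucleiTruth$semi_y_um,
            nucleiTruth$semi_x_um), voxel)
    dapi <- cpp_gauss_smooth(mask, dims, params@psfSigma / voxel) *
      params@dapiAmplitude
  } else {
    dapi <- array(0, dims)
  }
  chans[["DAPI"]] <- finish(dapi, params@noiseSd, seeds[1L])
  for (k in seq_along(params@channels)) {
    ch <- params@channels[k]
    sel <- which(spotsTruth$channel == ch)
    img <- array(0, dims)
    if (length(sel))
      img <- cpp_add_spots(img, dims,
        cbind(spotsTruth$z_um[sel], spotsTruth$y_um[sel],
              spotsTruth$x_um[sel]),
        params@psfSigma, params@spotAmplitude, voxel)
    chans[[ch]] <- finish(img, params@noiseSd, seeds[1L + k])
  }
  stack <- ImageStack(chans, voxel)
  truth <- new("GroundTruth", nuclei = nucleiTruth, spots = spotsTruth,
               perCellCounts = perCellTally(nucleiTruth, spotsTruth,
                                            params@channels))
  list(stack = stack, truth = truth)
}

#' Simulate a complete synthetic stack
#'
#' Convenience composition of \code{\link{generateNuclei}},
#' \code{\link{placeSpots}} and \code{\link{renderStack}} under the
#' per-stage child seeds derived from \code{params@seed}; the same params
#' (and seed) always regenerate the identical stack and ground truth.
#'
#' @param params a \linkS4class{SynthParams}.
#' @return list(stack = \linkS4class{ImageStack},
#'   truth = \linkS4class{GroundTruth}).
#' @examples
#' sim <- simulateStack(synthParams(nNuclei = 2L,
#'   gridShape = c(24L, 150L, 150L), seed = 3L))
#' perCellCounts(sim$truth)
#' @export
simulateStack <- function(params) {
  nucleiTruth <- generateNuclei(params)
  spotsTruth <- placeSpots(nucleiTruth, params)
  renderStack(nucleiTruth, spotsTruth, params)
}

#' Simulate a multi-stack, multi-group experiment
#'
#' Generates \code{nPerGroup} independent stacks for each experimental
#' group (e.g. two genotypes differing in the transcript load of one probe
#' channel). Per-stack seeds are derived deterministically from
#' \code{seed}, so the whole experiment is reproducible.
#'
#' @param groups named list of \linkS4class{SynthParams}, one per group.
#' @param nPerGroup stacks per group.
#' @param seed integer root seed for the experiment.
#' @return list of entries \code{list(group, id, stack, truth)}; \code{id}
#'   is \code{"<group>_<i>"}.
#' @examples
#' pc <- synthParams(nNuclei = 2L, gridShape = c(24L, 150L, 150L))
#' sims <- simulateExperiment(list(ctrl = pc), nPerGroup = 1L, seed = 2L)
#' sims[[1L]]$id
#' @export
simulateExperiment <- function(groups, nPerGroup = 5L, seed = 1L) {
  stopifnot(length(names(groups)) == length(groups))
  total <- length(groups) * nPerGroup
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, total))
  out <- vector("list", total)
  k <- 0L
  for (g in names(groups)) {
    for (i in seq_len(nPerGroup)) {
      k <- k + 1L
      p <- groups[[g]]
      p@seed <- seeds[k]
      sim <- simulateStack(p)
      out[[k]] <- list(group = g, id = paste0(g, "_", i),
                       stack = sim$stack, truth = sim$truth)
    }
  }
  out
}
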