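#' Anisotropy-corrected Gaussian smoothing
#'
#' Separable Gaussian filtering of a 3D volume with sigma given in
#' micrometres per axis; each axis sigma is converted to voxels using the
#' physical voxel size, so the blur is isotropic in physical space even on
#' anisotropic grids. Boundaries are handled by mirror reflection, which
#' preserves the mean intensity.
#'
#' @param volume numeric 3D array, dim (z, y, x).
#' @param sigma numeric(3) (or scalar) sigma in um per axis (z, y, x).
#' @param voxel numeric(3) um per voxel (z, y, x).
#' @return smoothed array, same dimensions.
#' @examples
#' v <- array(rnorm(4 * 16 * 16, 100, 5), c(4, 16, 16))
#' s <- smoothVolume(v, 0.3, c(0.5, 0.1, 0.1))
#' @export
smoothVolume <- function(volume, sigma, voxel) {
  stopIfNot3D(volume)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  if (any(sigma <= 0)) stop("sigma must be positive (um per axis)")
  if (length(voxel) != 3L || any(voxel <= 0))
    stop("voxel must be three positive um extents")
  cpp_gauss_smooth(volume, dim(volume), sigma / voxel)
}

#' Adaptive (local-mean) thresholding
#'
#' A voxel is foreground iff its intensity exceeds the mean over a
#' surrounding cubic window (side \code{adaptWindow} um, clipped at the
#' volume boundary) plus the offset. The offset is a strictness margin:
#' raising it shrinks the foreground monotonically. A fractional offset is
#' resolved against the volume's dynamic range (max - min) at call time.
#'
#' @param volume numeric 3D array (typically already smoothed).
#' @param config a \linkS4class{SegmentationConfig}.
#' @param voxel numeric(3) um per voxel (z, y, x).
#' @return logical 3D array (foreground mask).
#' @examples
#' v <- array(0, c(8, 32, 32)); v[4, 10:20, 10:20] <- 10
#' m <- adaptiveThreshold(v, segmentationConfig(adaptWindow = 2,
#'   adaptOffset = 1, offsetIsFraction = FALSE), c(0.5, 0.1, 0.1))
#' @export
adaptiveThreshold <- function(volume, config, voxel) {
  stopIfNot3D(volume)
  stopifnot(is(config, "SegmentationConfig"))
  wvox <- round(config@adaptWindow / voxel)
  if (any(wvox < 3))
    stop("adaptWindow of ", config@adaptWindow,
         " um spans fewer than 3 voxels along at least one axis ",
         "(voxel size ", paste(voxel, collapse = "/"), " um)")
  half <- as.integer(wvox %/% 2L)
  rng <- max(volume) - min(volume)
  if (rng == 0) # constant volume: nothing exceeds its own local mean
    return(array(FALSE, dim(volume)))
  off <- config@adaptOffset
  if (config@offsetIsFraction) off <- off * rng
  lm <- cpp_local_mean(volume, dim(volume), half)
  mask <- volume > lm + off
  dim(mask) <- dim(volume)
  mask
}

#' Label connected foreground objects
#'
#' 26-connected component labelling; components smaller than
#' \code{minVolume} (um^3) are removed. Labels are assigned 1..K in
#' raster-scan order of each component's first voxel, so the labelling is
#' deterministic.
#'
#' @param mask logical 3D array.
#' @param minVolume minimum object volume in um^3.
#' @param voxel numeric(3) um per voxel (z, y, x).
#' @return integer 3D array of labels (0 = background).
#' @examples
#' m <- array(FALSE, c(6, 12, 12)); m[2:4, 2:5, 2:5] <- TRUE
#' lab <- labelObjects(m, minVolume = 0.01, voxel = c(0.5, 0.1, 0.1))
#' max(lab)
#' @export
labelObjects <- function(mask, minVolume = 0, voxel = c(1, 1, 1)) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  lab <- cpp_label_components(as.logical(mask), dim(mask))
  if (minVolume > 0 && max(lab) > 0L) {
    voxvol <- prod(voxel)
    nvox <- tabulate(lab[lab > 0L])
    drop <- which(nvox * voxvol < minVolume)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      lab <- relabelScanOrder(lab)
    }
  }
  lab
}

# watershed seeds for one object: distance-transform local maxima,
# plateau-collapsed, then greedily thinned to a minimum separation (um),
# preferring higher distance values (ties by scan order)
splitSeeds <- function(dist, objMask, dims, voxel, minSep, minHeight) {
  mx <- cpp_local_maxima(dist, objMask, dims)
  mx <- mx & dist >= minHeight
  if (!any(mx)) return(integer(0))
  plateau <- cpp_label_components(mx, dims)
  nPl <- max(plateau)
  reps <- integer(nPl)
  for (p in seq_len(nPl)) reps[p] <- which(plateau == p)[1L]
  vals <- dist[reps]
  ord <- order(-vals, reps)
  reps <- reps[ord]
  coords <- function(i0) c((i0 %% dims[1L]),
                           (i0 %/% dims[1L]) %% dims[2L],
                           i0 %/% (dims[1L] * dims[2L]))
  kept <- integer(0)
  keptPos <- matrix(NA_real_, 0L, 3L)
  for (r in reps) {
    p <- voxelCenter(coords(r - 1L), voxel)
    if (nrow(keptPos) &&
        min(colSums((t(keptPos) - p)^2)) < minSep^2) next
    kept <- c(kept, r)
    keptPos <- rbind(keptPos, p)
  }
  kept
}

#' Split oversized labelled objects by watershed
#'
#' Objects whose volume exceeds \code{maxVolume} are re-segmented by
#' watershed on the negated (anisotropy-corrected) Euclidean distance
#' transform, seeded at distance-transform maxima at least
#' \code{seedMinSep} um apart and at least \code{seedMinHeight} um from
#' the object boundary. A compact object with a single qualifying distance
#' maximum therefore passes through unchanged, as do all objects at or
#' under \code{maxVolume}. Splitting never changes the set of foreground
#' voxels and never decreases the object count.
#'
#' @param labels integer 3D label array.
#' @param config a \linkS4class{SegmentationConfig}.
#' @param voxel numeric(3) um per voxel (z, y, x).
#' @return integer 3D label array, relabelled in scan order.
#' @examples
#' m <- array(FALSE, c(8, 30, 14)); m[3:6, 3:27, 3:12] <- TRUE
#' lab <- labelObjects(m, voxel = c(0.5, 0.1, 0.1))
#' sp <- splitOversized(lab, segmentationConfig(maxVolume = 0.5,
#'   seedMinSep = 0.4), c(0.5, 0.1, 0.1))
#' @export
splitOversized <- function(labels, config, voxel) {
  stopifnot(is(config, "SegmentationConfig"))
  if (max(labels) == 0L) return(labels)
  dims <- dim(labels)
  voxvol <- prod(voxel)
  nvox <- tabulate(labels[labels > 0L])
  big <- which(nvox * voxvol > config@maxVolume)
  if (!length(big)) return(labels)
  nextLabel <- max(labels) + 1L
  bbs <- cpp_label_bboxes(labels, dims, max(labels))
  for (L in big) {
    # bounding box with one-voxel pad so the object boundary is background
    bb <- bbs[L, ]
    z0 <- max(0L, bb[1L] - 1L); z1 <- min(dims[1L] - 1L, bb[2L] + 1L)
    y0 <- max(0L, bb[3L] - 1L); y1 <- min(dims[2L] - 1L, bb[4L] + 1L)
    x0 <- max(0L, bb[5L] - 1L); x1 <- min(dims[3L] - 1L, bb[6L] + 1L)
    sub <- labels[(z0:z1) + 1L, (y0:y1) + 1L, (x0:x1) + 1L, drop = FALSE]
    subMask <- sub == L
    sdim <- dim(subMask)
    dist <- cpp_edt(subMask, sdim, voxel)
    seeds <- splitSeeds(dist, subMask, sdim, voxel, config@seedMinSep,
                        config@seedMinHeight)
    if (length(seeds) < 2L) next
    seedArr <- array(0L, sdim)
    seedArr[seeds] <- seq_along(seeds)
    ws <- cpp_watershed(-dist, seedArr, subMask, sdim)
    newLab <- ifelse(ws > 1L, nextLabel + ws - 2L, L)
    nextLabel <- nextLabel + length(seeds) - 1L
    block <- labels[(z0:z1) + 1L, (y0:y1) + 1L, (x0:x1) + 1L, drop = FALSE]
    block[subMask] <- newLab[subMask]
    labels[(z0:z1) + 1L, (y0:y1) + 1L, (x0:x1) + 1L] <- block
  }
  relabelScanOrder(labels)
}

#' Segment nuclei from the DAPI channel
#'
#' Full nucleus-segmentation pipeline: Gaussian smoothing, adaptive
#' thresholding, 26-connected labelling with a minimum-volume filter, and
#' watershed splitting of oversized objects.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param dapiChannel name of the nuclear channel (default \code{"DAPI"}).
#' @param config a \linkS4class{SegmentationConfig}.
#' @return a \linkS4class{NucleusSet}.
#' @examples
#' sim <- simulateStack(synthParams(nNuclei = 2L,
#'   gridShape = c(24L, 150L, 150L), seed = 5L))
#' ns <- segmentNuclei(sim$stack)
#' nuclei(ns)
#' @export
segmentNuclei <- function(stack, dapiChannel = "DAPI",
                          config = segmentationConfig()) {
  stopifnot(is(stack, "ImageStack"))
  vol <- getChannel(stack, dapiChannel) # errors naming available channels
  voxel <- voxelSize(stack)
  sm <- smoothVolume(vol, config@smoothSigma, voxel)
  mask <- adaptiveThreshold(sm, config, voxel)
  lab <- labelObjects(mask, config@minVolume, voxel)
  lab <- splitOversized(lab, config, voxel)
  new("NucleusSet", labels = lab, table = labelStats(lab, voxel),
      voxelSize = voxel)
}
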