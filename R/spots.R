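# saddle-aware merging of watershed fragments: maxima whose separating
# saddle is shallower than minDepth below the lower peak are merged.
# Pairs are processed in decreasing saddle order with union-find, so
# chained plateaus merge correctly (single-linkage style).
mergeShallowFragments <- function(ws, vol, dims, minDepth) {
  nFrag <- max(ws)
  if (nFrag < 2L || minDepth <= 0) return(ws)
  sad <- cpp_region_saddles(ws, vol, dims)
  if (!nrow(sad)) return(ws)
  fg <- which(ws > 0L)
  peak <- vapply(split(vol[fg], factor(ws[fg], levels = seq_len(nFrag))),
                 max, 0)
  parent <- seq_len(nFrag)
  findRoot <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  ord <- order(-sad$saddle, sad$a, sad$b)
  for (i in ord) {
    ra <- findRoot(sad$a[i])
    rb <- findRoot(sad$b[i])
    if (ra == rb) next
    if (min(peak[ra], peak[rb]) - sad$saddle[i] < minDepth) {
      keep <- if (peak[ra] >= peak[rb]) ra else rb
      drop <- if (keep == ra) rb else ra
      parent[drop] <- keep
      peak[keep] <- max(peak[ra], peak[rb])
    }
  }
  roots <- vapply(seq_len(nFrag), findRoot, 1L)
  out <- ws
  out[ws > 0L] <- roots[ws[ws > 0L]]
  out
}

#' Detect transcript puncta in a probe channel
#'
#' Voxels above the intensity threshold are grouped into 26-connected
#' clusters; each cluster is split by watershed on the negated intensity,
#' seeded at intensity maxima, and fragments separated by a saddle
#' shallower than \code{watershedMinDepth} below the lower peak are merged
#' back. Fragments smaller than \code{minSpotVoxels} are discarded. Each
#' surviving fragment becomes one spot with an intensity-weighted 3D
#' centroid (um), voxel count and peak intensity.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param channel probe channel name.
#' @param config a \linkS4class{SpotConfig}.
#' @return \code{DataFrame} with columns \code{channel}, \code{z_um},
#'   \code{y_um}, \code{x_um}, \code{size_voxels}, \code{peak},
#'   \code{status} (\code{"unassigned"}), \code{nucleus} (\code{NA}),
#'   plus metadata column \code{threshold} recording the resolved
#'   absolute threshold.
#' @examples
#' sim <- simulateStack(synthParams(nNuclei = 1L,
#'   gridShape = c(24L, 120L, 120L), seed = 11L))
#' sp <- detectSpots(sim$stack, "Cre")
#' nrow(sp)
#' @export
detectSpots <- function(stack, channel, config = spotConfig()) {
  stopifnot(is(stack, "ImageStack"), is(config, "SpotConfig"))
  vol <- getChannel(stack, channel)
  voxel <- voxelSize(stack)
  dims <- dim(vol)
  thr <- config@threshold
  if (config@thresholdIsQuantile)
    thr <- cpp_quantile7(vol, config@threshold)
  mask <- vol > thr
  dim(mask) <- dims
  empty <- S4Vectors::DataFrame(channel = character(), z_um = numeric(),
                                y_um = numeric(), x_um = numeric(),
                                size_voxels = integer(), peak = numeric(),
                                status = character(), nucleus = integer())
  if (!any(mask)) {
    S4Vectors::metadata(empty) <- list(threshold = thr)
    return(empty)
  }
  # seeds: plateau-collapsed intensity maxima across all clusters at once
  mx <- cpp_local_maxima(vol, mask, dims)
  plateau <- cpp_label_components(mx, dims)
  seedArr <- array(0L, dims)
  pidx <- which(plateau > 0L) # ascending = scan order
  firsts <- pidx[!duplicated(plateau[pidx])]
  seedArr[firsts] <- plateau[firsts]
  ws <- cpp_watershed(-vol, seedArr, mask, dims)
  ws <- mergeShallowFragments(ws, vol, dims, config@watershedMinDepth)
  ws <- relabelScanOrder(ws)
  nFrag <- max(ws)
  if (nFrag == 0L) {
    S4Vectors::metadata(empty) <- list(threshold = thr)
    return(empty)
  }
  idx <- which(ws > 0L)
  lab <- ws[idx]
  wt <- vol[idx]
  nvox <- tabulate(lab, nFrag)
  keep <- which(nvox >= config@minSpotVoxels)
  i0 <- idx - 1L
  zc <- voxelCenter(i0 %% dims[1L], voxel[1L])
  yc <- voxelCenter((i0 %/% dims[1L]) %% dims[2L], voxel[2L])
  xc <- voxelCenter(i0 %/% (dims[1L] * dims[2L]), voxel[3L])
  wsum <- rowsum(wt, lab)[, 1L]
  zw <- rowsum(wt * zc, lab)[, 1L] / wsum
  yw <- rowsum(wt * yc, lab)[, 1L] / wsum
  xw <- rowsum(wt * xc, lab)[, 1L] / wsum
  pk <- vapply(split(wt, lab), max, 0)
  out <- S4Vectors::DataFrame(channel = rep(channel, length(keep)),
                              z_um = unname(zw[keep]),
                              y_um = unname(yw[keep]),
                              x_um = unname(xw[keep]),
                              size_voxels = nvox[keep],
                              peak = unname(pk[keep]),
                              status = rep("unassigned", length(keep)),
                              nucleus = rep(NA_integer_, length(keep)))
  S4Vectors::metadata(out) <- list(threshold = thr)
  out
}

#' Tally spot sizes
#'
#' Exact histogram of spot sizes (voxel counts); the counts always sum to
#' the number of spots.
#'
#' @param spots a spot \code{DataFrame} from \code{\link{detectSpots}}.
#' @return \code{DataFrame} with columns \code{size_voxels}, \code{count},
#'   sorted by size.
#' @examples
#' df <- S4Vectors::DataFrame(size_voxels = c(4L, 4L, 7L))
#' spotSizeHistogram(df)
#' @export
spotSizeHistogram <- function(spots) {
  if (!nrow(spots))
    return(S4Vectors::DataFrame(size_voxels = integer(), count = integer()))
  tb <- table(spots$size_voxels)
  S4Vectors::DataFrame(size_voxels = as.integer(names(tb)),
                       count = as.integer(tb))
}
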