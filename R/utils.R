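# Internal helpers: seeded evaluation and voxel/physical conversions.

# Evaluate expr with a temporary RNG state; the caller's RNG is untouched.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage child seeds from one root seed, so stages can be
# regenerated independently.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Physical position (um) of the centre of 0-based voxel index i.
voxelCenter <- function(index0, voxel) (index0 + 0.5) * voxel

# 0-based voxel index containing physical position p (um), clamped to grid.
voxelIndex <- function(p, voxel, n) pmin(pmax(floor(p / voxel), 0), n - 1)

# um sigma/extent -> voxels, per axis.
umToVox <- function(um, voxel) um / voxel

stopIfNot3D <- function(volume) {
  if (length(dim(volume)) != 3L)
    stop("expected a 3D array with dim (z, y, x)")
  if (!all(is.finite(volume))) stop("intensities must be finite")
  invisible(volume)
}

# Per-label voxel counts and physical centroids from a label array.
# Returns a DataFrame ordered by label.
labelStats <- function(labels, voxel) {
  idx <- which(labels > 0L)
  if (!length(idx))
    return(S4Vectors::DataFrame(label = integer(), centroid_z_um = numeric(),
                                centroid_y_um = numeric(),
                                centroid_x_um = numeric(),
                                volume_um3 = numeric()))
  d <- dim(labels)
  lab <- labels[idx]
  i0 <- idx - 1L
  z <- i0 %% d[1L]
  y <- (i0 %/% d[1L]) %% d[2L]
  x <- i0 %/% (d[1L] * d[2L])
  nvox <- tabulate(lab)
  keep <- which(nvox > 0L)
  voxvol <- prod(voxel)
  cz <- rowsum(voxelCenter(z, voxel[1L]), lab)[, 1L]
  cy <- rowsum(voxelCenter(y, voxel[2L]), lab)[, 1L]
  cx <- rowsum(voxelCenter(x, voxel[3L]), lab)[, 1L]
  S4Vectors::DataFrame(label = keep,
                       centroid_z_um = unname(cz / nvox[keep]),
                       centroid_y_um = unname(cy / nvox[keep]),
                       centroid_x_um = unname(cx / nvox[keep]),
                       volume_um3 = nvox[keep] * voxvol)
}

# Relabel a label array so labels are 1..K in raster-scan order of each
# object's first voxel; drops empty labels.
relabelScanOrder <- function(labels) {
  idx <- which(labels > 0L)
  if (!length(idx)) return(labels)
  first <- !duplicated(labels[idx])
  order_map <- integer(max(labels))
  order_map[labels[idx][first]] <- seq_len(sum(first))
  labels[idx] <- order_map[labels[idx]]
  labels
}
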