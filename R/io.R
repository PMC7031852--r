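#' Write an ImageStack as a multi-page TIFF with a metadata sidecar
#'
#' Pages are interleaved channel-fastest: page index = channel + nChannels
#' * zPlane (both 0-based), i.e. all channels of z-plane 1, then all
#' channels of z-plane 2, and so on. Because baseline TIFF carries no
#' voxel-size tag, the voxel size, channel order and intensity range are
#' written to a plain-text YAML sidecar \code{<path>.meta.yaml}.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @param clipMax full-scale intensity (defaults to 65535, 16-bit).
#' @return invisibly, the sidecar path.
#' @examples
#' st <- ImageStack(list(DAPI = array(100, c(2, 8, 8))), c(0.5, 0.1, 0.1))
#' f <- tempfile(fileext = ".tif")
#' writeStack(st, f)
#' @export
writeStack <- function(stack, path, clipMax = 65535) {
  stopifnot(is(stack, "ImageStack"))
  chn <- channelNames(stack)
  d <- dim(stack@channels[[1L]])
  pages <- vector("list", d[1L] * length(chn))
  k <- 0L
  for (z in seq_len(d[1L])) {
    for (ch in chn) {
      k <- k + 1L
      pages[[k]] <- stack@channels[[ch]][z, , ] / clipMax
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  side <- paste0(path, ".meta.yaml")
  yaml::write_yaml(list(
    voxel_size_um = list(z = stack@voxelSize[1L], y = stack@voxelSize[2L],
                         x = stack@voxelSize[3L]),
    channels = as.list(chn),
    page_order = "channel-fastest",
    clip_max = clipMax), side)
  invisible(side)
}

#' Read a multi-page TIFF into an ImageStack
#'
#' Demultiplexes pages by the declared channel order (channel-fastest
#' interleaving, see \code{\link{writeStack}}). Channel names and voxel
#' size come from the \code{<path>.meta.yaml} sidecar when present;
#' explicit arguments win over the sidecar, with a warning when the two
#' disagree.
#'
#' @param path TIFF path.
#' @param channels channel names in page order (overrides the sidecar).
#' @param voxelSize numeric(3) um per voxel (z, y, x) (overrides the
#'   sidecar).
#' @param clipMax full-scale intensity (overrides the sidecar).
#' @return an \linkS4class{ImageStack}.
#' @examples
#' st <- ImageStack(list(DAPI = array(100, c(2, 8, 8))), c(0.5, 0.1, 0.1))
#' f <- tempfile(fileext = ".tif")
#' writeStack(st, f)
#' st2 <- readStack(f)
#' @export
readStack <- function(path, channels = NULL, voxelSize = NULL,
                      clipMax = NULL) {
  side <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else NULL
  pick <- function(given, fromMeta, what) {
    if (is.null(given)) {
      if (is.null(fromMeta))
        stop(what, " not given and no metadata sidecar found for ", path)
      fromMeta
    } else {
      if (!is.null(fromMeta) && !isTRUE(all.equal(unname(given),
                                                  unname(fromMeta))))
        warning(what, " differs between the call and the sidecar of ",
                path, "; using the explicitly supplied value")
      given
    }
  }
  channels <- pick(channels,
                   if (is.null(meta)) NULL else unlist(meta$channels),
                   "channels")
  voxelSize <- pick(voxelSize,
                    if (is.null(meta)) NULL else
                      unlist(meta$voxel_size_um[c("z", "y", "x")]),
                    "voxelSize")
  clipMax <- if (is.null(clipMax)) {
    if (is.null(meta$clip_max)) 65535 else meta$clip_max
  } else clipMax
  pages <- tiff::readTIFF(path, all = TRUE)
  nC <- length(channels)
  if (length(pages) %% nC != 0L)
    stop("page count ", length(pages), " is not divisible by the declared ",
         nC, " channel(s)")
  nz <- length(pages) %/% nC
  d2 <- dim(pages[[1L]])
  chans <- setNames(
    lapply(seq_len(nC), function(ci) {
      a <- array(0, c(nz, d2[1L], d2[2L]))
      for (z in seq_len(nz))
        a[z, , ] <- round(pages[[(z - 1L) * nC + ci]] * clipMax)
      a
    }), channels)
  ImageStack(chans, voxelSize)
}

#' Blind image identities for unbiased quantification
#'
#' Deterministic, seeded bijection from image identifiers to opaque codes
#' of the form \code{B<digits>}. The codes carry no group information:
#' construction fails if any code would contain a group label as a
#' substring (or vice versa). The inverse map should be written to a
#' separate key file (see \code{\link{writeBlindKey}}) that the analysis
#' never reads.
#'
#' @param paths unique image identifiers (paths or ids).
#' @param seed integer seed.
#' @param groupLabels optional group labels to leak-check against.
#' @return named character vector: \code{paths -> codes}.
#' @examples
#' blindImages(c("a.tif", "b.tif"), seed = 1)
#' @export
blindImages <- function(paths, seed, groupLabels = NULL) {
  if (anyDuplicated(paths))
    stop("image identifiers must be unique")
  n <- length(paths)
  codes <- sprintf("B%04d", withSeed(seed, sample.int(9999L, n)))
  for (g in unique(groupLabels)) {
    if (any(grepl(g, codes, fixed = TRUE)) ||
        any(vapply(codes, grepl, TRUE, x = g, fixed = TRUE)))
      stop("blinded codes would leak group label '", g, "'")
  }
  setNames(codes, paths)
}

#' Write the blinding key
#'
#' @param blindMap output of \code{\link{blindImages}}.
#' @param file CSV path for the key (id, code).
#' @param groups optional group label per id, stored in the key only.
#' @return invisibly, \code{file}.
#' @export
writeBlindKey <- function(blindMap, file, groups = NULL) {
  df <- data.frame(id = names(blindMap), code = unname(blindMap))
  if (!is.null(groups)) df$group <- groups
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
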