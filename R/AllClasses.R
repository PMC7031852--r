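#' ImageStack: a multi-channel 3D voxel grid with physical voxel size
#'
#' Container for one confocal field of view. Each channel is a numeric 3D
#' array with dimensions ordered (z, y, x); all channels share one grid and
#' one physical voxel size in micrometres per axis. The physical position of
#' the centre of voxel index \code{i} (0-based) along an axis is
#' \code{(i + 0.5) * voxelSize} -- this convention is used by every
#' geometric computation in the package.
#'
#' @slot channels named list of numeric 3D arrays, identical dimensions.
#' @slot voxelSize numeric(3), micrometres per voxel along (z, y, x).
#'
#' @aliases ImageStack-class
#' @exportClass ImageStack
setClass("ImageStack",
  representation(channels = "list", voxelSize = "numeric"))

setValidity("ImageStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel is required")
  if (is.null(names(ch)) || anyDuplicated(names(ch)) || any(names(ch) == ""))
    return("channels must be uniquely named")
  dims <- lapply(ch, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("every channel must be a 3D array")
  if (!all(vapply(dims, identical, TRUE, dims[[1L]])))
    return("all channels must share the same dimensions")
  v <- object@voxelSize
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
    return("voxelSize must be three positive values (z, y, x) in um")
  TRUE
})

#' Construct an ImageStack
#'
#' @param channels named list of numeric 3D arrays, dimensions (z, y, x).
#' @param voxelSize micrometres per voxel along (z, y, x).
#' @return An \linkS4class{ImageStack}.
#' @examples
#' st <- ImageStack(list(DAPI = array(0, c(4, 8, 8))),
#'                  voxelSize = c(0.5, 0.1, 0.1))
#' channelNames(st)
#' @export
ImageStack <- function(channels, voxelSize) {
  new("ImageStack", channels = channels,
      voxelSize = as.numeric(voxelSize))
}

#' NucleusSet: labelled 3D nuclei and their summary table
#'
#' Result of nucleus segmentation: an integer label array (0 = background,
#' 1..K = nuclei, voxel sets pairwise disjoint by construction) together
#' with a per-nucleus table of centroid (um) and volume (um^3).
#'
#' @slot labels integer 3D array of nucleus labels.
#' @slot table \link[S4Vectors]{DataFrame} with columns \code{label},
#'   \code{centroid_z_um}, \code{centroid_y_um}, \code{centroid_x_um},
#'   \code{volume_um3}.
#' @slot voxelSize micrometres per voxel (z, y, x).
#'
#' @aliases NucleusSet-class
#' @exportClass NucleusSet
setClass("NucleusSet",
  representation(labels = "array", table = "DataFrame",
                 voxelSize = "numeric"))

setValidity("NucleusSet", function(object) {
  tb <- object@table
  need <- c("label", "centroid_z_um", "centroid_y_um", "centroid_x_um",
            "volume_um3")
  if (!all(need %in% colnames(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$label)) return("nucleus labels must be unique")
  present <- sort(unique(as.integer(object@labels)))
  present <- present[present > 0L]
  if (!setequal(present, tb$label))
    return("table labels must match labels present in the array")
  TRUE
})

#' Accessors for NucleusSet
#'
#' @param x a \linkS4class{NucleusSet}.
#' @return \code{nuclei()} returns the per-nucleus \code{DataFrame};
#'   \code{labelArray()} the integer label array.
#' @name NucleusSet-accessors
NULL

#' SynthParams: synthetic-acquisition parameters
#'
#' Describes one simulated confocal field: grid, voxel size, the nucleus
#' population, per-channel transcript load, optical blur and camera noise.
#' Defaults emulate a 63x confocal z-series through a 16 um tissue section
#' with DAPI-stained near-spherical nuclei and diffraction-limited puncta.
#'
#' @slot gridShape integer(3) voxels per axis (z, y, x).
#' @slot voxelSize numeric(3) um per voxel (z, y, x).
#' @slot nNuclei number of nuclei to place.
#' @slot radiusRange numeric(2) min/max ellipsoid semi-axis (um); each
#'   semi-axis is drawn independently, so nuclei are non-identical.
#' @slot touchingFraction fraction of nuclei placed with their surface
#'   within one voxel of a neighbour (exercises watershed splitting).
#' @slot channels probe channel names (the DAPI channel is always added).
#' @slot spotsPerCell named list (one per channel) of integer(2) min/max
#'   transcripts per nucleus, drawn uniformly.
#' @slot extranuclearRate expected free (unowned) spots per 1000 um^3,
#'   per channel (Poisson).
#' @slot psfSigma numeric(3) Gaussian PSF sigma (um) per axis (z, y, x).
#' @slot spotAmplitude punctum peak intensity above background.
#' @slot dapiAmplitude nuclear DAPI intensity above background.
#' @slot backgroundLevel constant background intensity.
#' @slot noiseSd additive Gaussian noise sd.
#' @slot shotNoise logical; add Poisson shot noise on top (off by default).
#' @slot minSpotSep minimum distance (um) between ground-truth spots of the
#'   same channel, so puncta are optically resolvable.
#' @slot innerMargin ground-truth spots are placed at least this far (um)
#'   inside their nucleus surface (keeps ownership unambiguous under
#'   voxelised segmentation).
#' @slot outerMargin free spots are placed at least this far (um) outside
#'   every nucleus surface.
#' @slot clipMax intensities clipped to [0, clipMax] and rounded
#'   (unsigned 16-bit range by default).
#' @slot seed integer root RNG seed; per-stage child seeds are derived
#'   from it deterministically.
#'
#' @aliases SynthParams-class
#' @exportClass SynthParams
setClass("SynthParams",
  representation(gridShape = "integer", voxelSize = "numeric",
                 nNuclei = "integer", radiusRange = "numeric",
                 touchingFraction = "numeric", channels = "character",
                 spotsPerCell = "list", extranuclearRate = "numeric",
                 psfSigma = "numeric", spotAmplitude = "numeric",
                 dapiAmplitude = "numeric", backgroundLevel = "numeric",
                 noiseSd = "numeric", shotNoise = "logical",
                 minSpotSep = "numeric", innerMargin = "numeric",
                 outerMargin = "numeric", clipMax = "numeric",
                 seed = "integer"))

setValidity("SynthParams", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    return("gridShape must be three positive voxel counts (z, y, x)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive um extents")
  if (object@nNuclei < 0L) return("nNuclei must be >= 0")
  if (length(object@radiusRange) != 2L || any(object@radiusRange <= 0) ||
      diff(object@radiusRange) < 0)
    return("radiusRange must be positive (min, max) um")
  if (object@touchingFraction < 0 || object@touchingFraction > 1)
    return("touchingFraction must be in [0, 1]")
  if (length(object@channels) == 0L || anyDuplicated(object@channels))
    return("channels must be distinct names")
  if ("DAPI" %in% object@channels)
    return("'DAPI' is reserved for the nuclear channel")
  if (!setequal(names(object@spotsPerCell), object@channels))
    return("spotsPerCell must be named by channel")
  for (ch in object@channels) {
    r <- object@spotsPerCell[[ch]]
    if (length(r) != 2L || any(r < 0) || r[1L] > r[2L])
      return("each spotsPerCell entry must be 0 <= min <= max")
  }
  if (object@extranuclearRate < 0) return("extranuclearRate must be >= 0")
  if (any(object@psfSigma <= 0)) return("psfSigma must be positive")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@clipMax <= 0) return("clipMax must be positive")
  TRUE
})

#' Synthetic acquisition parameters with field defaults
#'
#' Defaults define the package's standard validation fixture: a
#' 16 x 32 x 32 um field (0.5 x 0.1 x 0.1 um voxels, 63x-confocal-like
#' anisotropy), 50 near-spherical nuclei of semi-axes 2.2-2.5 um with 20%
#' placed touching a neighbour, two probe channels (\code{Cre}, \code{Wt1})
#' with 3-8 transcripts per nucleus, 5 free transcripts per 1000 um^3,
#' diffraction-limited puncta (PSF sigma 0.4/0.15/0.15 um) of peak
#' amplitude 3000 over background 500 with Gaussian noise sd 100, clipped
#' to 16-bit.
#'
#' @param gridShape,voxelSize,nNuclei,radiusRange,touchingFraction,channels
#'   see \linkS4class{SynthParams}.
#' @param spotsPerCell,extranuclearRate,psfSigma,spotAmplitude,dapiAmplitude
#'   see \linkS4class{SynthParams}.
#' @param backgroundLevel,noiseSd,shotNoise,minSpotSep,innerMargin see
#'   \linkS4class{SynthParams}.
#' @param outerMargin,clipMax,seed see \linkS4class{SynthParams}.
#' @return A \linkS4class{SynthParams}.
#' @examples
#' p <- synthParams(nNuclei = 5L, gridShape = c(24L, 120L, 120L), seed = 1L)
#' @export
synthParams <- function(gridShape = c(32L, 320L, 320L),
                        voxelSize = c(0.5, 0.1, 0.1),
                        nNuclei = 50L,
                        radiusRange = c(2.2, 2.5),
                        touchingFraction = 0.2,
                        channels = c("Cre", "Wt1"),
                        spotsPerCell = NULL,
                        extranuclearRate = 5,
                        psfSigma = c(0.4, 0.15, 0.15),
                        spotAmplitude = 3000,
                        dapiAmplitude = 3000,
                        backgroundLevel = 500,
                        noiseSd = 100,
                        shotNoise = FALSE,
                        minSpotSep = 1.25,
                        innerMargin = 0.4,
                        outerMargin = 1.5,
                        clipMax = 65535,
                        seed = 1L) {
  if (is.null(spotsPerCell))
    spotsPerCell <- setNames(rep(list(c(3L, 8L)), length(channels)),
                             channels)
  new("SynthParams", gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize), nNuclei = as.integer(nNuclei),
      radiusRange = as.numeric(radiusRange),
      touchingFraction = as.numeric(touchingFraction),
      channels = as.character(channels),
      spotsPerCell = lapply(spotsPerCell, as.integer),
      extranuclearRate = as.numeric(extranuclearRate),
      psfSigma = as.numeric(psfSigma),
      spotAmplitude = as.numeric(spotAmplitude),
      dapiAmplitude = as.numeric(dapiAmplitude),
      backgroundLevel = as.numeric(backgroundLevel),
      noiseSd = as.numeric(noiseSd), shotNoise = as.logical(shotNoise),
      minSpotSep = as.numeric(minSpotSep),
      innerMargin = as.numeric(innerMargin),
      outerMargin = as.numeric(outerMargin), clipMax = as.numeric(clipMax),
      seed = as.integer(seed))
}

#' GroundTruth: exhaustive truth for a synthetic stack
#'
#' @slot nuclei \code{DataFrame}: \code{label}, centroid (um) and
#'   semi-axes (um) per nucleus.
#' @slot spots \code{DataFrame}: \code{channel}, true centroid (um) and
#'   \code{owner} (nucleus label, \code{NA} for free spots).
#' @slot perCellCounts integer matrix, nuclei x channels, the intended
#'   transcript count per cell; always equals the tally of owned spots.
#'
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(nuclei = "DataFrame", spots = "DataFrame",
                 perCellCounts = "matrix"))

setValidity("GroundTruth", function(object) {
  sp <- object@spots
  owners <- sp$owner[!is.na(sp$owner)]
  if (length(owners) && !all(owners %in% object@nuclei$label))
    return("every spot owner must be an existing nucleus label")
  # conservation: perCellCounts is the tally of owned spots
  pc <- object@perCellCounts
  if (nrow(object@nuclei)) {
    tal <- matrix(0L, nrow(object@nuclei), ncol(pc),
                  dimnames = dimnames(pc))
    if (nrow(sp)) {
      ok <- !is.na(sp$owner)
      if (any(ok)) {
        t2 <- table(factor(sp$owner[ok], levels = object@nuclei$label),
                    factor(sp$channel[ok], levels = colnames(pc)))
        tal[] <- as.integer(t2)
      }
    }
    if (!identical(unname(tal), unname(pc)))
      return("perCellCounts must equal the tally of owned spots")
  }
  TRUE
})

#' SegmentationConfig: nucleus-segmentation parameters
#'
#' @slot smoothSigma numeric(3) Gaussian sigma (um) per axis (z, y, x).
#' @slot adaptWindow side (um) of the cubic local-mean window.
#' @slot adaptOffset strictness margin: a voxel is foreground iff its
#'   (smoothed) intensity exceeds the local mean plus this offset. Either
#'   an absolute intensity or, when \code{offsetIsFraction}, a fraction of
#'   the volume's dynamic range resolved at run time.
#' @slot offsetIsFraction logical flag for \code{adaptOffset}.
#' @slot minVolume reject labelled objects smaller than this (um^3).
#' @slot maxVolume split objects larger than this (um^3) by watershed on
#'   the negated distance transform.
#' @slot seedMinSep minimum separation (um) between watershed seeds when
#'   splitting (roughly the smallest expected centre-to-centre distance of
#'   touching nuclei, i.e. about 1.6 times the minimum nucleus radius).
#' @slot seedMinHeight minimum distance-transform value (um) for a seed:
#'   candidate maxima closer than this to the object boundary are surface
#'   bumps, not nucleus centres.
#'
#' @aliases SegmentationConfig-class
#' @exportClass SegmentationConfig
setClass("SegmentationConfig",
  representation(smoothSigma = "numeric", adaptWindow = "numeric",
                 adaptOffset = "numeric", offsetIsFraction = "logical",
                 minVolume = "numeric", maxVolume = "numeric",
                 seedMinSep = "numeric", seedMinHeight = "numeric"))

setValidity("SegmentationConfig", function(object) {
  if (any(object@smoothSigma <= 0)) return("smoothSigma must be positive")
  if (object@adaptWindow <= 0) return("adaptWindow must be positive")
  if (object@adaptOffset < 0) return("adaptOffset must be >= 0")
  if (object@minVolume <= 0 || object@maxVolume <= 0)
    return("volumes must be positive")
  if (object@minVolume >= object@maxVolume)
    return("minVolume must be smaller than maxVolume")
  if (object@seedMinSep <= 0) return("seedMinSep must be positive")
  if (object@seedMinHeight < 0) return("seedMinHeight must be >= 0")
  TRUE
})

#' Nucleus-segmentation configuration with defaults
#'
#' The volume gate (\code{minVolume}, \code{maxVolume}) must bracket the
#' singleton-nucleus volume distribution: objects above \code{maxVolume}
#' are candidates for watershed splitting (a compact object with a single
#' distance maximum passes through intact), objects below \code{minVolume}
#' are discarded as debris. Defaults match nuclei of semi-axes about
#' 2.2-2.5 um (volumes 45-65 um^3) after the dilation that adaptive
#' thresholding of a blurred boundary introduces.
#'
#' @param smoothSigma,adaptWindow,adaptOffset,offsetIsFraction see
#'   \linkS4class{SegmentationConfig}.
#' @param minVolume,maxVolume,seedMinSep,seedMinHeight see
#'   \linkS4class{SegmentationConfig}.
#' @return A \linkS4class{SegmentationConfig}.
#' @examples
#' segmentationConfig(maxVolume = 120)
#' @export
segmentationConfig <- function(smoothSigma = c(0.5, 0.5, 0.5),
                               adaptWindow = 6,
                               adaptOffset = 0.15,
                               offsetIsFraction = TRUE,
                               minVolume = 15,
                               maxVolume = 75,
                               seedMinSep = 3.5,
                               seedMinHeight = 1.5) {
  new("SegmentationConfig", smoothSigma = as.numeric(smoothSigma),
      adaptWindow = as.numeric(adaptWindow),
      adaptOffset = as.numeric(adaptOffset),
      offsetIsFraction = as.logical(offsetIsFraction),
      minVolume = as.numeric(minVolume), maxVolume = as.numeric(maxVolume),
      seedMinSep = as.numeric(seedMinSep),
      seedMinHeight = as.numeric(seedMinHeight))
}

#' SpotConfig: transcript-detection parameters
#'
#' @slot threshold intensity threshold for transcript detection; an
#'   absolute intensity, or a quantile of the channel when
#'   \code{thresholdIsQuantile}.
#' @slot thresholdIsQuantile logical flag for \code{threshold}.
#' @slot minSpotVoxels discard fragments with fewer voxels than this.
#' @slot watershedMinDepth merge criterion: two intensity maxima in one
#'   supra-threshold cluster stay separate spots only if the saddle
#'   between them is at least this far below the lower peak.
#'
#' @aliases SpotConfig-class
#' @exportClass SpotConfig
setClass("SpotConfig",
  representation(threshold = "numeric", thresholdIsQuantile = "logical",
                 minSpotVoxels = "integer", watershedMinDepth = "numeric"))

setValidity("SpotConfig", function(object) {
  if (object@thresholdIsQuantile &&
      (object@threshold <= 0 || object@threshold >= 1))
    return("quantile threshold must be in (0, 1)")
  if (object@minSpotVoxels < 1L) return("minSpotVoxels must be >= 1")
  if (object@watershedMinDepth < 0)
    return("watershedMinDepth must be >= 0")
  TRUE
})

#' Spot-detection configuration with defaults
#'
#' The default threshold is the 0.995 quantile of the channel, a
#' reproducible stand-in for a manually chosen intensity cutoff; override
#' with an absolute value per channel when calibrated thresholds exist.
#' \code{minSpotVoxels = 2} rejects single-voxel noise, the weakest
#' defensible size filter. \code{watershedMinDepth} should exceed a few
#' noise standard deviations so noise ripples on one punctum are not split
#' into two.
#'
#' @param threshold,thresholdIsQuantile,minSpotVoxels,watershedMinDepth
#'   see \linkS4class{SpotConfig}.
#' @return A \linkS4class{SpotConfig}.
#' @examples
#' spotConfig(threshold = 1200, thresholdIsQuantile = FALSE)
#' @export
spotConfig <- function(threshold = 0.995,
                       thresholdIsQuantile = TRUE,
                       minSpotVoxels = 2L,
                       watershedMinDepth = 400) {
  new("SpotConfig", threshold = as.numeric(threshold),
      thresholdIsQuantile = as.logical(thresholdIsQuantile),
      minSpotVoxels = as.integer(minSpotVoxels),
      watershedMinDepth = as.numeric(watershedMinDepth))
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@channels[[1L]])
  cat("ImageStack:", paste(d, collapse = " x "), "voxels (z, y, x),",
      length(object@channels), "channel(s)\n")
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
  cat("  voxel size (um):", paste(object@voxelSize, collapse = " x "), "\n")
})

setMethod("show", "NucleusSet", function(object) {
  cat("NucleusSet:", nrow(object@table), "nuclei in a",
      paste(dim(object@labels), collapse = " x "), "grid\n")
  if (nrow(object@table))
    cat("  volume (um^3): median",
        signif(stats::median(object@table$volume_um3), 4), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@nuclei), "nuclei,",
      nrow(object@spots), "spots (",
      sum(is.na(object@spots$owner)), "free )\n")
})

setMethod("show", "SynthParams", function(object) {
  cat("SynthParams:", paste(object@gridShape, collapse = " x "),
      "voxels,", object@nNuclei, "nuclei, channels:",
      paste(object@channels, collapse = ", "), "\n")
})
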