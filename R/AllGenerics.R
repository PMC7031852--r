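#' @rdname ImageStack-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ImageStack-accessors
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname ImageStack-accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname NucleusSet-accessors
#' @export
setGeneric("nuclei", function(x) standardGeneric("nuclei"))

#' @rdname NucleusSet-accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' Accessors for ImageStack
#'
#' @param x an \linkS4class{ImageStack} (or \linkS4class{NucleusSet} for
#'   \code{voxelSize}).
#' @param channel channel name.
#' @return \code{channelNames()}: character vector; \code{getChannel()}:
#'   the channel's 3D array; \code{voxelSize()}: numeric(3) um per voxel
#'   (z, y, x).
#' @examples
#' st <- ImageStack(list(DAPI = array(0, c(4, 8, 8))), c(0.5, 0.1, 0.1))
#' voxelSize(st)
#' @name ImageStack-accessors
NULL

#' @rdname ImageStack-accessors
#' @export
setMethod("channelNames", "ImageStack", function(x) names(x@channels))

#' @rdname ImageStack-accessors
#' @export
setMethod("getChannel", "ImageStack", function(x, channel) {
  if (!channel %in% names(x@channels))
    stop("channel '", channel, "' not found; available: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[channel]]
})

#' @rdname ImageStack-accessors
#' @export
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)

#' @rdname NucleusSet-accessors
#' @export
setMethod("voxelSize", "NucleusSet", function(x) x@voxelSize)

#' @rdname NucleusSet-accessors
#' @export
setMethod("nuclei", "NucleusSet", function(x) x@table)

#' @rdname NucleusSet-accessors
#' @export
setMethod("labelArray", "NucleusSet", function(x) x@labels)

#' @rdname GroundTruth-accessors
#' @export
setGeneric("trueNuclei", function(x) standardGeneric("trueNuclei"))

#' @rdname GroundTruth-accessors
#' @export
setGeneric("trueSpots", function(x) standardGeneric("trueSpots"))

#' @rdname GroundTruth-accessors
#' @export
setGeneric("perCellCounts", function(x) standardGeneric("perCellCounts"))

#' Accessors for GroundTruth
#'
#' @param x a \linkS4class{GroundTruth}.
#' @return \code{trueNuclei()} / \code{trueSpots()}: \code{DataFrame}s;
#'   \code{perCellCounts()}: integer matrix nuclei x channels.
#' @name GroundTruth-accessors
NULL

#' @rdname GroundTruth-accessors
#' @export
setMethod("trueNuclei", "GroundTruth", function(x) x@nuclei)

#' @rdname GroundTruth-accessors
#' @export
setMethod("trueSpots", "GroundTruth", function(x) x@spots)

#' @rdname GroundTruth-accessors
#' @export
setMethod("perCellCounts", "GroundTruth", function(x) x@perCellCounts)
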