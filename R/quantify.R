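#' Assign detected spots to nuclei in 3D
#'
#' A spot is assigned to nucleus L iff the voxel containing its
#' (intensity-weighted) centroid carries label L in the segmentation;
#' spots whose centroid voxel is background are excluded. Every spot
#' receives exactly one terminal status, so
#' assigned + excluded = detected.
#'
#' @param spots spot \code{DataFrame} from \code{\link{detectSpots}}.
#' @param nucleusSet a \linkS4class{NucleusSet}.
#' @return the spot \code{DataFrame} with \code{status}
#'   (\code{"assigned"} / \code{"excluded"}) and \code{nucleus} resolved.
#' @examples
#' ## see vignette for an end-to-end example
#' @export
assignSpots <- function(spots, nucleusSet) {
  stopifnot(is(nucleusSet, "NucleusSet"))
  if (!nrow(spots)) return(spots)
  lab <- labelArray(nucleusSet)
  voxel <- voxelSize(nucleusSet)
  d <- dim(lab)
  zi <- voxelIndex(spots$z_um, voxel[1L], d[1L])
  yi <- voxelIndex(spots$y_um, voxel[2L], d[2L])
  xi <- voxelIndex(spots$x_um, voxel[3L], d[3L])
  owner <- lab[cbind(zi + 1L, yi + 1L, xi + 1L)]
  spots$nucleus <- ifelse(owner > 0L, owner, NA_integer_)
  spots$status <- ifelse(owner > 0L, "assigned", "excluded")
  spots
}

#' Build per-cell transcript-count profiles
#'
#' One profile per segmented nucleus (zero-count nuclei included): counts
#' tally assigned spots by (nucleus, channel); excluded spots contribute
#' nowhere. Returned as a \link[SummarizedExperiment]{SummarizedExperiment}
#' with nuclei as rows (their centroid/volume in \code{rowData}), channels
#' as columns, and a \code{counts} assay.
#'
#' @param spots assigned spot \code{DataFrame}
#'   (from \code{\link{assignSpots}}).
#' @param nucleusSet a \linkS4class{NucleusSet}.
#' @param channels channel names to tally (columns of the result).
#' @return a \code{SummarizedExperiment} with assay \code{counts}.
#' @examples
#' ## see vignette for an end-to-end example
#' @export
cellCounts <- function(spots, nucleusSet, channels) {
  stopifnot(is(nucleusSet, "NucleusSet"))
  tb <- nuclei(nucleusSet)
  asg <- spots[nrow(spots) > 0 & spots$status == "assigned", , drop = FALSE]
  if (nrow(asg) && !all(asg$nucleus %in% tb$label))
    stop("assigned spot references an unknown nucleus label: ",
         "segmentation and assignment are out of sync")
  m <- matrix(0L, nrow(tb), length(channels),
              dimnames = list(as.character(tb$label), channels))
  if (nrow(asg)) {
    t2 <- table(factor(asg$nucleus, levels = tb$label),
                factor(asg$channel, levels = channels))
    m[] <- as.integer(t2)
  }
  SummarizedExperiment(assays = list(counts = m), rowData = tb)
}

#' Call per-cell gene positivity
#'
#' A cell is positive for a channel iff its assigned transcript count
#' exceeds \code{k}; the default \code{k = 2} implements the
#' "more than two transcripts" rule, i.e. counts 0-2 are negative and 3+
#' positive.
#'
#' @param profiles \code{SummarizedExperiment} from
#'   \code{\link{cellCounts}}.
#' @param k nonnegative integer positivity threshold.
#' @return \code{profiles} with an added logical assay \code{positive}.
#' @examples
#' m <- matrix(c(0L, 2L, 3L, 5L), 4, 1,
#'             dimnames = list(1:4, "Cre"))
#' se <- SummarizedExperiment::SummarizedExperiment(list(counts = m))
#' SummarizedExperiment::assay(callPositive(se, k = 2), "positive")
#' @export
callPositive <- function(profiles, k = 2L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L)
    stop("positivity threshold k must be a single nonnegative integer")
  cnt <- assay(profiles, "counts")
  pos <- cnt > k
  assays(profiles)[["positive"]] <- pos
  S4Vectors::metadata(profiles)$positivity_threshold <- k
  profiles
}

#' Target-channel counts in reporter-positive cells
#'
#' Restricts the target-channel transcript counts to the cells that are
#' positive for the reporter channel (e.g. Wt1 counts within Cre-positive
#' cells). Requires \code{\link{callPositive}} to have been applied.
#'
#' @param profiles \code{SummarizedExperiment} with assays \code{counts}
#'   and \code{positive}.
#' @param reporterChannel channel defining the cell population.
#' @param targetChannel channel whose counts are returned.
#' @return numeric vector, one entry per reporter-positive cell.
#' @examples
#' m <- matrix(c(3L, 2L, 4L, 5L, 9L, 0L), 3, 2,
#'             dimnames = list(1:3, c("Cre", "Wt1")))
#' se <- SummarizedExperiment::SummarizedExperiment(list(counts = m))
#' coexpressionCounts(callPositive(se, 2), "Cre", "Wt1")
#' @export
coexpressionCounts <- function(profiles, reporterChannel, targetChannel) {
  cnt <- assay(profiles, "counts")
  for (ch in c(reporterChannel, targetChannel))
    if (!ch %in% colnames(cnt))
      stop("channel '", ch, "' not in profiles; available: ",
           paste(colnames(cnt), collapse = ", "))
  if (!"positive" %in% names(assays(profiles)))
    stop("profiles lack a 'positive' assay; run callPositive() first")
  pos <- assay(profiles, "positive")[, reporterChannel]
  unname(cnt[pos, targetChannel])
}

#' Two-group comparison with Student's t test
#'
#' Unpaired pooled-variance (Student) two-sample t test, the test used for
#' all two-group comparisons in this pipeline; Welch's unequal-variance
#' form is available behind \code{varEqual = FALSE}.
#'
#' @param countsA,countsB numeric vectors (e.g. per-cell transcript
#'   counts), each of length >= 2.
#' @param varEqual pool the variance (Student, default) or not (Welch).
#' @return list with elements \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{mean_diff} (mean(A) - mean(B)), \code{mean_a}, \code{mean_b},
#'   \code{n_a}, \code{n_b}.
#' @examples
#' compareGroups(c(1, 2), c(3, 4))
#' @export
compareGroups <- function(countsA, countsB, varEqual = TRUE) {
  if (length(countsA) < 2L || length(countsB) < 2L)
    stop("each group needs at least 2 observations")
  if (varEqual) {
    na <- length(countsA); nb <- length(countsB)
    sp2 <- ((na - 1) * stats::var(countsA) + (nb - 1) * stats::var(countsB)) /
      (na + nb - 2)
    if (sp2 <= 0)
      stop("pooled variance is zero: the t statistic is undefined")
  } else if (stats::var(countsA) == 0 && stats::var(countsB) == 0) {
    stop("both group variances are zero: the t statistic is undefined")
  }
  ht <- t.test(countsA, countsB, var.equal = varEqual)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(diff(rev(ht$estimate))),
       mean_a = unname(ht$estimate[1L]), mean_b = unname(ht$estimate[2L]),
       n_a = length(countsA), n_b = length(countsB))
}
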