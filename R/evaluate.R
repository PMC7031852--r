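#' Compare a pipeline result against synthetic ground truth
#'
#' Matches detected nuclei to ground-truth nuclei one-to-one by nearest
#' centroid (greedy in increasing distance, capped at
#' \code{maxMatchDist}), then scores nucleus recovery, per-cell count
#' agreement and positivity concordance.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param nucleusSet the \linkS4class{NucleusSet} from
#'   \code{\link{segmentNuclei}}.
#' @param profiles the \code{SummarizedExperiment} from
#'   \code{\link{cellCounts}} (positivity assay optional; counts are
#'   re-thresholded with \code{k}).
#' @param k positivity threshold used for the concordance score.
#' @param maxMatchDist maximum centroid distance (um) for a match.
#' @return list with \code{n_true}, \code{n_detected},
#'   \code{count_error_pct} (percent deviation of the detected nucleus
#'   count), \code{n_matched}, \code{median_centroid_error_um},
#'   \code{count_exact_pct} (percent of matched (cell, channel) entries
#'   whose transcript count equals truth), \code{count_exact_isolated_pct}
#'   (the same restricted to isolated nuclei -- surface more than half a
#'   micrometre from every neighbour -- whose spots cannot straddle a
#'   split boundary), and \code{positivity_concordance_pct} (percent of
#'   matched (cell, channel) entries with identical positivity calls).
#' @examples
#' ## see vignette for an end-to-end example
#' @export
evaluateRecovery <- function(truth, nucleusSet, profiles, k = 2L,
                             maxMatchDist = 1.5) {
  tn <- trueNuclei(truth)
  dn <- nuclei(nucleusSet)
  nTrue <- nrow(tn)
  nDet <- nrow(dn)
  out <- list(n_true = nTrue, n_detected = nDet,
              count_error_pct = if (nTrue) 100 * abs(nDet - nTrue) / nTrue
                                else NA_real_,
              n_matched = 0L,
              median_centroid_error_um = NA_real_,
              count_exact_pct = NA_real_,
              count_exact_isolated_pct = NA_real_,
              positivity_concordance_pct = NA_real_)
  if (!nTrue || !nDet) return(out)
  tc <- cbind(tn$centroid_z_um, tn$centroid_y_um, tn$centroid_x_um)
  dc <- cbind(dn$centroid_z_um, dn$centroid_y_um, dn$centroid_x_um)
  dmat <- outer(rowSums(tc^2), rep(1, nDet)) +
    outer(rep(1, nTrue), rowSums(dc^2)) - 2 * tc %*% t(dc)
  dmat <- sqrt(pmax(dmat, 0))
  # greedy one-to-one matching in increasing distance
  ord <- order(dmat)
  usedT <- logical(nTrue)
  usedD <- logical(nDet)
  matchT <- integer(0)
  matchD <- integer(0)
  for (o in ord) {
    if (dmat[o] > maxMatchDist) break
    ti <- (o - 1L) %% nTrue + 1L
    di <- (o - 1L) %/% nTrue + 1L
    if (usedT[ti] || usedD[di]) next
    usedT[ti] <- usedD[di] <- TRUE
    matchT <- c(matchT, ti)
    matchD <- c(matchD, di)
  }
  if (!length(matchT)) return(out)
  out$n_matched <- length(matchT)
  out$median_centroid_error_um <-
    median(dmat[cbind(matchT, matchD)])
  cnt <- assay(profiles, "counts")
  pc <- perCellCounts(truth)
  chans <- intersect(colnames(pc), colnames(cnt))
  detRow <- match(as.character(dn$label[matchD]), rownames(cnt))
  trueRow <- match(as.character(tn$label[matchT]), rownames(pc))
  cm <- cnt[detRow, chans, drop = FALSE]
  tm <- pc[trueRow, chans, drop = FALSE]
  out$count_exact_pct <- 100 * mean(cm == tm)
  out$positivity_concordance_pct <- 100 * mean((cm > k) == (tm > k))
  # isolated nuclei: surface gap > 0.5 um to every other nucleus, so no
  # spot sits near a watershed split boundary
  if (all(c("semi_z_um", "semi_y_um", "semi_x_um") %in% colnames(tn))) {
    sa <- cbind(tn$semi_z_um, tn$semi_y_um, tn$semi_x_um)
    iso <- rep(TRUE, nTrue)
    for (i in seq_len(nTrue)) {
      for (j in seq_len(nTrue)) {
        if (i == j) next
        dv <- tc[j, ] - tc[i, ]
        dd <- sqrt(sum(dv^2))
        u <- dv / dd
        ri <- 1 / sqrt(sum(u * u / (sa[i, ] * sa[i, ])))
        rj <- 1 / sqrt(sum(u * u / (sa[j, ] * sa[j, ])))
        if (dd - ri - rj < 0.5) { iso[i] <- FALSE; break }
      }
    }
    isoSel <- iso[matchT]
    if (any(isoSel))
      out$count_exact_isolated_pct <-
        100 * mean(cm[isoSel, , drop = FALSE] == tm[isoSel, , drop = FALSE])
  }
  out
}

#' Write ground truth as plain CSV tables
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param nucleiFile,spotsFile output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeGroundTruth <- function(truth, nucleiFile, spotsFile) {
  write.csv(as.data.frame(trueNuclei(truth)), nucleiFile,
            row.names = FALSE)
  write.csv(as.data.frame(trueSpots(truth)), spotsFile, row.names = FALSE)
  invisible(c(nucleiFile, spotsFile))
}
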