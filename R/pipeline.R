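#' Pipeline configuration
#'
#' Bundles every parameter of the end-to-end quantification: channel
#' roles, segmentation and spot-detection settings, the positivity rule,
#' the reporter/target pair for coexpression summaries, and the seed. All
#' resolved values are serialised into the run log, so a run is fully
#' reproducible from its log.
#'
#' @param probeChannels probe channel names to quantify.
#' @param dapiChannel nuclear channel name (exactly one).
#' @param segmentation a \linkS4class{SegmentationConfig}.
#' @param spot a \linkS4class{SpotConfig} applied to every probe channel,
#'   or a named list with one \linkS4class{SpotConfig} per probe channel.
#' @param k positivity threshold (a cell is positive iff count > k).
#' @param reporterChannel,targetChannel optional pair for the
#'   "target counts within reporter-positive cells" summary.
#' @param seed integer seed for blinding and synthetic generation.
#' @return a config list of class \code{smfish_pipeline_config}.
#' @examples
#' cfg <- pipelineConfig(probeChannels = c("Cre", "Wt1"),
#'                       reporterChannel = "Cre", targetChannel = "Wt1")
#' @export
pipelineConfig <- function(probeChannels = c("Cre", "Wt1"),
                           dapiChannel = "DAPI",
                           segmentation = segmentationConfig(),
                           spot = spotConfig(),
                           k = 2L,
                           reporterChannel = NULL,
                           targetChannel = NULL,
                           seed = 1L) {
  if (length(dapiChannel) != 1L)
    stop("exactly one DAPI channel is required")
  if (is(spot, "SpotConfig"))
    spot <- setNames(rep(list(spot), length(probeChannels)), probeChannels)
  if (!all(probeChannels %in% names(spot)))
    stop("every probe channel needs a SpotConfig")
  structure(list(probeChannels = probeChannels, dapiChannel = dapiChannel,
                 segmentation = segmentation, spot = spot,
                 k = as.integer(k), reporterChannel = reporterChannel,
                 targetChannel = targetChannel, seed = as.integer(seed)),
            class = "smfish_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the \code{\link{pipelineConfig}}
#' arguments; \code{segmentation} and \code{spot} sub-maps are passed to
#' \code{\link{segmentationConfig}} / \code{\link{spotConfig}}. Missing
#' keys keep their defaults.
#'
#' @param path YAML file.
#' @return a config list of class \code{smfish_pipeline_config}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- if (is.null(y$segmentation)) segmentationConfig() else
    do.call(segmentationConfig, y$segmentation)
  spot <- if (is.null(y$spot)) spotConfig() else
    if (!is.null(names(y$spot)) && all(vapply(y$spot, is.list, TRUE)))
      lapply(y$spot, function(s) do.call(spotConfig, s)) else
      do.call(spotConfig, y$spot)
  pipelineConfig(
    probeChannels = if (is.null(y$probeChannels)) c("Cre", "Wt1") else
      unlist(y$probeChannels),
    dapiChannel = if (is.null(y$dapiChannel)) "DAPI" else y$dapiChannel,
    segmentation = seg, spot = spot,
    k = if (is.null(y$k)) 2L else y$k,
    reporterChannel = y$reporterChannel,
    targetChannel = y$targetChannel,
    seed = if (is.null(y$seed)) 1L else y$seed)
}

# quantify one stack under a config: segment, detect, assign, count, call.
# errors abort with the stage name and the (blinded) image identifier.
quantifyStack <- function(stack, config, id = "stack") {
  step <- function(stage, expr)
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed for image ", id, ": ",
           conditionMessage(e), call. = FALSE))
  ns <- step("segment",
             segmentNuclei(stack, config$dapiChannel, config$segmentation))
  spots <- step("detect+assign", do.call(rbind,
    lapply(config$probeChannels, function(ch)
      assignSpots(detectSpots(stack, ch, config$spot[[ch]]), ns))))
  profiles <- step("count+call",
                   callPositive(cellCounts(spots, ns, config$probeChannels),
                                config$k))
  list(nuclei = ns, spots = spots, profiles = profiles)
}

#' Run the full blinded quantification pipeline
#'
#' Executes blind, segment, detect, assign, count, call, unblind and
#' compare on a set of stacks, either read from disk or simulated. Group
#' comparisons (two groups required) use the pooled-variance t test on
#' three summaries per probe channel: all per-cell counts, per-stack mean
#' counts, and -- when a reporter/target pair is configured -- per-cell
#' target counts within reporter-positive cells.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param images data.frame with columns \code{path} and \code{group};
#'   stacks are read with \code{\link{readStack}}.
#' @param synthetic alternative input: list with elements \code{groups}
#'   (named list of \linkS4class{SynthParams}) and \code{nPerGroup};
#'   stacks are simulated with \code{\link{simulateExperiment}} under
#'   \code{config$seed}.
#' @param outputDir optional directory; when given, writes
#'   \code{nuclei.csv}, \code{spots.csv}, \code{cells.csv},
#'   \code{comparison.csv}, \code{blind_key.csv} and \code{run_log.txt}.
#' @return invisibly, a result bundle: list with data.frames
#'   \code{nuclei}, \code{spots}, \code{cells}, \code{comparison}, the
#'   \code{blindKey}, and \code{profiles} (per-stack
#'   \code{SummarizedExperiment}s named by blinded code).
#' @examples
#' ## see vignette; a minimal synthetic run:
#' p <- synthParams(nNuclei = 2L, gridShape = c(24L, 150L, 150L))
#' res <- runPipeline(pipelineConfig(seed = 4L),
#'   synthetic = list(groups = list(g1 = p, g2 = p), nPerGroup = 1L))
#' @export
runPipeline <- function(config, images = NULL, synthetic = NULL,
                        outputDir = NULL) {
  stopifnot(inherits(config, "smfish_pipeline_config"))
  if (is.null(images) && is.null(synthetic))
    stop("no input: supply 'images' or 'synthetic'")
  if (!is.null(images) && nrow(images) == 0L)
    stop("zero input images")
  if (!is.null(outputDir))
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(synthetic)) {
    sims <- simulateExperiment(synthetic$groups,
                               nPerGroup = synthetic$nPerGroup,
                               seed = config$seed)
    ids <- vapply(sims, `[[`, "", "id")
    groups <- vapply(sims, `[[`, "", "group")
    stacks <- lapply(sims, `[[`, "stack")
  } else {
    ids <- as.character(images$path)
    groups <- as.character(images$group)
    stacks <- NULL # read lazily below
  }
  if (!length(ids)) stop("zero input images")

  blindMap <- blindImages(ids, seed = config$seed, groupLabels = groups)
  # analysis proceeds in blinded-code order, without group identity
  ord <- order(unname(blindMap))
  nucleiRows <- list()
  spotRows <- list()
  cellRows <- list()
  profiles <- list()
  for (j in ord) {
    code <- unname(blindMap[j])
    stack <- if (is.null(stacks)) {
      tryCatch(readStack(ids[j]), error = function(e)
        stop("stage 'read' failed for image ", code, ": ",
             conditionMessage(e), call. = FALSE))
    } else stacks[[j]]
    q <- quantifyStack(stack, config, id = code)
    tb <- as.data.frame(nuclei(q$nuclei))
    if (nrow(tb)) nucleiRows[[code]] <- cbind(code = code, tb)
    sp <- as.data.frame(q$spots)
    if (nrow(sp)) spotRows[[code]] <- cbind(code = code, sp)
    cnt <- assay(q$profiles, "counts")
    pos <- assay(q$profiles, "positive")
    if (nrow(cnt)) {
      cells <- data.frame(code = code,
                          label = as.integer(rownames(cnt)))
      for (ch in colnames(cnt)) {
        cells[[paste0(ch, "_count")]] <- cnt[, ch]
        cells[[paste0(ch, "_positive")]] <- pos[, ch]
      }
      cellRows[[code]] <- cells
    }
    profiles[[code]] <- q$profiles
  }
  nucleiDf <- if (length(nucleiRows)) do.call(rbind, nucleiRows) else
    data.frame()
  spotsDf <- if (length(spotRows)) do.call(rbind, spotRows) else
    data.frame()
  cellsDf <- if (length(cellRows)) do.call(rbind, cellRows) else
    data.frame()
  rownames(nucleiDf) <- rownames(spotsDf) <- rownames(cellsDf) <- NULL

  # unblind and compare
  codeGroup <- setNames(groups, unname(blindMap[ids]))
  codeId <- setNames(ids, unname(blindMap[ids]))
  if (nrow(cellsDf)) {
    cellsDf$id <- unname(codeId[cellsDf$code])
    cellsDf$group <- unname(codeGroup[cellsDf$code])
  }
  grpNames <- sort(unique(groups))
  comparison <- data.frame()
  if (length(grpNames) == 2L && nrow(cellsDf)) {
    ga <- grpNames[1L]; gb <- grpNames[2L]
    addRow <- function(channel, summary, va, vb) {
      if (length(va) < 2L || length(vb) < 2L) return(NULL)
      r <- tryCatch(compareGroups(va, vb), error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(channel = channel, summary = summary,
                 group_a = ga, group_b = gb, n_a = r$n_a, n_b = r$n_b,
                 mean_a = r$mean_a, mean_b = r$mean_b,
                 mean_diff = r$mean_diff, t = r$t, df = r$df, p = r$p)
    }
    rows <- list()
    for (ch in config$probeChannels) {
      cntCol <- paste0(ch, "_count")
      va <- cellsDf[[cntCol]][cellsDf$group == ga]
      vb <- cellsDf[[cntCol]][cellsDf$group == gb]
      rows <- c(rows, list(addRow(ch, "per_cell", va, vb)))
      ma <- tapply(cellsDf[[cntCol]][cellsDf$group == ga],
                   cellsDf$code[cellsDf$group == ga], mean)
      mb <- tapply(cellsDf[[cntCol]][cellsDf$group == gb],
                   cellsDf$code[cellsDf$group == gb], mean)
      rows <- c(rows, list(addRow(ch, "per_stack_mean",
                                  as.numeric(ma), as.numeric(mb))))
    }
    if (!is.null(config$reporterChannel) &&
        !is.null(config$targetChannel)) {
      repPos <- cellsDf[[paste0(config$reporterChannel, "_positive")]]
      tc <- paste0(config$targetChannel, "_count")
      va <- cellsDf[[tc]][repPos & cellsDf$group == ga]
      vb <- cellsDf[[tc]][repPos & cellsDf$group == gb]
      rows <- c(rows, list(addRow(config$targetChannel,
                                  "per_cell_reporter_positive", va, vb)))
    }
    comparison <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(comparison)) comparison <- data.frame()
  }

  bundle <- list(nuclei = nucleiDf, spots = spotsDf, cells = cellsDf,
                 comparison = comparison, blindKey = blindMap,
                 profiles = profiles)

  if (!is.null(outputDir)) {
    write.csv(nucleiDf, file.path(outputDir, "nuclei.csv"),
              row.names = FALSE)
    write.csv(spotsDf, file.path(outputDir, "spots.csv"),
              row.names = FALSE)
    write.csv(cellsDf, file.path(outputDir, "cells.csv"),
              row.names = FALSE)
    write.csv(comparison, file.path(outputDir, "comparison.csv"),
              row.names = FALSE)
    writeBlindKey(blindMap, file.path(outputDir, "blind_key.csv"),
                  groups = groups)
    writeRunLog(config, ids, groups, file.path(outputDir, "run_log.txt"))
  }
  invisible(bundle)
}

# serialise every resolved parameter and seed: the log alone reproduces
# the run
writeRunLog <- function(config, ids, groups, file) {
  seg <- config$segmentation
  lines <- c(
    paste0("smFISHcoloc ", as.character(utils::packageVersion("smFISHcoloc"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("seed: ", config$seed),
    paste0("dapiChannel: ", config$dapiChannel),
    paste0("probeChannels: ", paste(config$probeChannels, collapse = ", ")),
    paste0("positivity k: ", config$k),
    paste0("reporter/target: ",
           paste(c(config$reporterChannel, config$targetChannel),
                 collapse = " / ")),
    paste0("segmentation: smoothSigma=",
           paste(seg@smoothSigma, collapse = "/"),
           " adaptWindow=", seg@adaptWindow,
           " adaptOffset=", seg@adaptOffset,
           if (seg@offsetIsFraction) " (fraction of dynamic range)" else "",
           " minVolume=", seg@minVolume, " maxVolume=", seg@maxVolume,
           " seedMinSep=", seg@seedMinSep),
    vapply(names(config$spot), function(ch) {
      s <- config$spot[[ch]]
      paste0("spot[", ch, "]: threshold=", s@threshold,
             if (s@thresholdIsQuantile) " (quantile)" else "",
             " minSpotVoxels=", s@minSpotVoxels,
             " watershedMinDepth=", s@watershedMinDepth)
    }, ""),
    paste0("images: ", length(ids)),
    paste0("  ", ids, " [", groups, "]"))
  writeLines(lines, file)
  invisible(file)
}
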