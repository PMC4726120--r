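#' Build an analysis configuration
#'
#' Collects every tunable of the analysis pipeline in one (YAML-serializable)
#' list. `mode` selects the experiment type: `"live_ddr"` and `"live_frap"`
#' segment the first frame, track nuclei and build MS time courses;
#' `"fixed_if"` deactivates tracking and recognizes nuclei on a DNA
#' (Hoechst) counterstain channel of a fixed sample, measuring MS on the
#' signal channel in a single frame.
#'
#' @param mode `"live_ddr"`, `"live_frap"` or `"fixed_if"`.
#' @param linesPerField stripes per field (sets the nominal gauge).
#' @param stripeWidthPx user-defined stripe width in pixels.
#' @param dRange,pWindowPx gauge search range and offset window; `NULL`
#'   derives them from the nominal gauge via [defaultDRange()] /
#'   [defaultPWindow()] once the frame height is known.
#' @param segmentation a [SegmentationConfig-class].
#' @param searchRadiusPx,maxCarry,trackingBridgeSigmaPx tracking tunables
#'   (see [trackNuclei()]); `trackingBridgeSigmaPx = NULL` derives the
#'   stripe-bridging sigma as a quarter of the nominal gauge.
#' @param alpha significance level used downstream in comparisons.
#' @return A list of class `striationConfig`.
#' @export
analysisConfig <- function(mode = c("live_ddr", "live_frap", "fixed_if"),
                           linesPerField = 32L, stripeWidthPx = 5,
                           dRange = NULL, pWindowPx = NULL,
                           segmentation = segmentationConfig(),
                           searchRadiusPx = 25, maxCarry = 2L,
                           trackingBridgeSigmaPx = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  structure(list(
    mode = mode, linesPerField = as.integer(linesPerField),
    stripeWidthPx = stripeWidthPx, dRange = dRange, pWindowPx = pWindowPx,
    segmentation = segmentation, searchRadiusPx = searchRadiusPx,
    maxCarry = as.integer(maxCarry),
    trackingBridgeSigmaPx = trackingBridgeSigmaPx, alpha = alpha),
    class = "striationConfig")
}

#' Analyze one field of view end to end
#'
#' Runs segmentation (first frame, or DNA channel for fixed samples),
#' tracking (live modes), per-frame stripe fitting and MS computation, and
#' curve-parameter extraction. The analysis is deterministic: identical
#' inputs and configuration give identical outputs.
#'
#' @param stack a [FrameStack-class] (the signal channel).
#' @param config an [analysisConfig()] list.
#' @param dnaFrame DNA-channel matrix, required for `mode = "fixed_if"`.
#' @param fieldId identifier recorded in the output tables.
#' @return List with `ms` (the long MS table), `params` (per-nucleus curve
#'   parameters; empty for fixed mode), `tracks` and `log` (named counts:
#'   nuclei found, tracks lost, fit failures).
#' @export
analyzeStack <- function(stack, config = analysisConfig(), dnaFrame = NULL,
                         fieldId = "field1") {
  stopifnot(inherits(config, "striationConfig"))
  nr <- nrow(getFrame(stack, 1L))
  dRange <- if (is.null(config$dRange))
    defaultDRange(nr, config$linesPerField) else config$dRange
  pWin <- if (is.null(config$pWindowPx))
    defaultPWindow(nr, config$linesPerField) else config$pWindowPx

  if (config$mode == "fixed_if") {
    if (is.null(dnaFrame)) stop("fixed_if mode requires a DNA-channel frame")
    masks <- segmentHoechst(dnaFrame, config$segmentation)
    ms <- do.call(rbind, lapply(masks, function(m) {
      cut <- cutNucleus(getFrame(stack, 1L), m)
      rv <- rotateToVertical(cut$image, cut$mask)
      fit <- fitStripes(rv$image, rv$mask, config$stripeWidthPx, dRange, pWin)
      fit@angleDeg <- rv$angleDeg
      cbind(data.frame(nucleus_id = m@nucleusId, frame = 1L,
                       time_min = timesMin(stack)[1L]),
            computeMS(rv$image, rv$mask, fit))
    }))
    tracks <- list()
  } else {
    masks <- segmentCascade(getFrame(stack, 1L), config$segmentation)
    if (length(masks) == 0L) {
      warning("no nuclei found in the first frame", call. = FALSE)
      return(list(ms = emptyMsTable(), params = data.frame(), tracks = list(),
                  log = c(nuclei_found = 0L, tracks_lost = 0L, fit_failures = 0L)))
    }
    bridge <- if (is.null(config$trackingBridgeSigmaPx))
      max(2, round(nr / config$linesPerField / 4)) else config$trackingBridgeSigmaPx
    tracks <- trackNuclei(stack, masks, config$searchRadiusPx,
                          config$segmentation, config$maxCarry,
                          bridgeSigmaPx = bridge)
    direction <- if (config$mode == "live_frap") "dark" else "bright"
    ms <- do.call(rbind, lapply(tracks, msSeries, stack = stack,
                                widthPx = config$stripeWidthPx,
                                dRange = dRange, pWindowPx = pWin,
                                direction = direction))
  }
  ms <- cbind(data.frame(field_id = fieldId), ms)
  params <- if (config$mode == "live_ddr") curveParams(ms, "DDR")
    else if (config$mode == "live_frap") curveParams(ms, "FRAP")
    else data.frame()
  list(ms = ms, params = params, tracks = tracks,
       log = c(nuclei_found = length(masks),
               tracks_lost = sum(vapply(tracks, isLost, logical(1))),
               fit_failures = sum(ms$flagged, na.rm = TRUE)))
}

emptyMsTable <- function() {
  cols <- c("field_id", "nucleus_id", "frame", "time_min", "ms", "j_meas",
            "j_expt", "stripe_D", "stripe_P", "angle_deg", "f_value", "flagged")
  as.data.frame(stats::setNames(lapply(cols, function(x) logical(0)), cols))
}

#' Render a synthetic scene to files
#'
#' Writes the rendered stack (16-bit multi-page TIFF), the frame-times
#' sidecar, the ground-truth label stack, a ground-truth JSON (trajectories,
#' programmed MS, kinetic parameters, stripe geometry) and a manifest
#' recording the configuration and its hash, for reproducible re-analysis.
#'
#' @param cfg a [SceneConfig-class] (or path to a YAML file of
#'   [sceneConfig()] arguments).
#' @param outDir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
runSimulate <- function(cfg, outDir) {
  if (is.character(cfg)) cfg <- do.call(sceneConfig, yaml::read_yaml(cfg))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sc <- renderScene(cfg)
  paths <- c(stack = file.path(outDir, "stack.tif"),
             times = file.path(outDir, "times.csv"),
             labels = file.path(outDir, "labels.tif"),
             truth = file.path(outDir, "ground_truth.json"),
             manifest = file.path(outDir, "manifest.yaml"))
  writeStack(sc$stack, paths[["stack"]], timesPath = paths[["times"]])
  writeStack(frameStack(lapply(sc$truth@labels, function(m) {
    storage.mode(m) <- "double"; m
  }), timesMin(sc$stack)), paths[["labels"]])
  jsonlite::write_json(list(
    mode = sc$truth@mode,
    gauge_px = sc$truth@gaugePx,
    width_px = sc$truth@widthPx,
    stripe_center_rows = sc$truth@stripeCenterRows,
    times_min = timesMin(sc$stack),
    ms_true = sc$truth@msTrue,
    trajectories = sc$truth@trajectories,
    kinetics = sc$truth@kinetics
  ), paths[["truth"]], digits = NA, auto_unbox = TRUE)
  cfgList <- sceneConfigAsList(cfg)
  cfgYaml <- yaml::as.yaml(cfgList)
  yaml::write_yaml(list(
    config = cfgList,
    config_md5 = digestString(cfgYaml),
    seed = cfg@seed,
    files = as.list(basename(paths[names(paths) != "manifest"]))
  ), paths[["manifest"]])
  invisible(paths)
}

sceneConfigAsList <- function(cfg) {
  nms <- slotNames(class(cfg))
  stats::setNames(lapply(nms, function(nm) {
    v <- slot(cfg, nm)
    if (is.numeric(v) || is.integer(v)) as.vector(v) else v
  }), nms)
}

# md5 of a string via the file-based tools helper (no extra dependency)
digestString <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(x, tf, eos = NULL)
  unname(tools::md5sum(tf))
}

#' Analyze a stack on disk and write result tables
#'
#' Reads the stack and its frame times, runs [analyzeStack()], and writes the
#' per-record MS table, the per-nucleus curve-parameter table and a run log
#' (counts plus the effective configuration) into `outDir`.
#'
#' @param stackPath multi-page TIFF of the signal channel.
#' @param timesPath frame-times sidecar CSV (column `time_min`).
#' @param config an [analysisConfig()] list or path to a YAML file of its
#'   arguments.
#' @param outDir output directory.
#' @param dnaPath optional DNA-channel TIFF (required for `fixed_if`).
#' @param fieldId field identifier for the tables.
#' @return Invisibly, the named vector of written paths.
#' @export
runAnalyze <- function(stackPath, timesPath, config = analysisConfig(),
                       outDir, dnaPath = NULL, fieldId = "field1") {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    segArgs <- args$segmentation
    args$segmentation <- if (is.null(segArgs)) segmentationConfig()
      else do.call(segmentationConfig, segArgs)
    config <- do.call(analysisConfig, args)
  }
  stack <- readStack(stackPath, timesPath)
  dnaFrame <- if (!is.null(dnaPath)) getFrame(readStack(dnaPath, timesMin(stack)[1L]), 1L)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- analyzeStack(stack, config, dnaFrame = dnaFrame, fieldId = fieldId)
  paths <- c(ms = file.path(outDir, "ms_table.csv"),
             params = file.path(outDir, "curve_params.csv"),
             log = file.path(outDir, "run_log.yaml"))
  writeMSTable(res$ms, paths[["ms"]])
  utils::write.csv(res$params, paths[["params"]], row.names = FALSE)
  yaml::write_yaml(list(counts = as.list(res$log),
                        mode = config$mode,
                        n_frames = nFrames(stack),
                        field_id = fieldId), paths[["log"]])
  invisible(paths)
}

#' Compare treated curve parameters against mock from files
#'
#' Reads per-nucleus curve-parameter CSVs (one or more biological replicates
#' per condition; technical duplicates should already be pooled into one file
#' or are pooled here by row-binding), runs [compareToMock()] with the
#' replicate concordance rule, and writes the comparison table.
#'
#' @param treatedPaths,mockPaths character vectors of curve-parameter CSVs;
#'   with more than one path per condition, path order pairs the biological
#'   replicates and the concordance rule applies.
#' @param outPath output CSV path.
#' @param alpha significance level (default 0.05).
#' @param minCells minimum recommended cells per condition.
#' @return Invisibly, the comparison data.frame (also written to `outPath`).
#' @export
runCompare <- function(treatedPaths, mockPaths, outPath, alpha = 0.05,
                       minCells = 100L) {
  readAll <- function(paths) do.call(rbind, lapply(seq_along(paths), function(i) {
    d <- utils::read.csv(paths[[i]])
    d$replicate <- i
    d
  }))
  if (length(mockPaths) == 0L || !all(file.exists(unlist(mockPaths))))
    stop("missing mock curve-parameter file(s)")
  cmp <- compareToMock(readAll(treatedPaths), readAll(mockPaths),
                       alpha = alpha, minCells = minCells)
  utils::write.csv(cmp, outPath, row.names = FALSE)
  invisible(cmp)
}
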