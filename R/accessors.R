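#' Construct a FrameStack
#'
#' @param frames list of numeric matrices (one per time point) or a single
#'   matrix for a one-frame stack.
#' @param timesMin acquisition times in minutes relative to micro-irradiation;
#'   strictly increasing, first entry at or before 0.
#' @param pixelSizeUm optional physical pixel size in micrometres.
#' @param channelLabel optional channel description.
#' @return A [FrameStack-class] object.
#' @examples
#' fs <- frameStack(list(matrix(1, 8, 8), matrix(2, 8, 8)), timesMin = c(0, 5))
#' nFrames(fs)
#' @export
frameStack <- function(frames, timesMin, pixelSizeUm = NA_real_, channelLabel = "") {
  if (is.matrix(frames)) frames <- list(frames)
  new("FrameStack",
    frames = frames, timesMin = as.numeric(timesMin),
    pixelSizeUm = as.numeric(pixelSizeUm), channelLabel = channelLabel)
}

#' @describeIn frameStack number of frames in a stack.
#' @param x a `FrameStack`.
#' @export
nFrames <- function(x) length(x@frames)

#' @describeIn frameStack extract frame `i` as a numeric matrix.
#' @param i frame index.
#' @export
getFrame <- function(x, i) x@frames[[i]]

#' @describeIn frameStack acquisition times in minutes.
#' @export
timesMin <- function(x) x@timesMin

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf("FrameStack: %d frame(s) of %d x %d px, t = %s min\n",
    length(object@frames), d[1L], d[2L],
    paste(signif(object@timesMin, 4), collapse = ", ")))
  if (nzchar(object@channelLabel))
    cat("  channel:", object@channelLabel, "\n")
})

#' Construct a SegmentationConfig
#'
#' See [SegmentationConfig-class] for the meaning and defaults of every
#' tunable of the threshold-cascade nucleus finder.
#'
#' @param thresholdStartQuantile,thresholdDecayFactor,thresholdFloorQuantile
#'   cascade schedule parameters.
#' @param minAreaPx,maxAreaPx,minSolidity size and solidity gates.
#' @param excludeBorder drop masks touching the frame border.
#' @param smoothingSigmaPx Gaussian pre-smoothing sigma (0 = none).
#' @param growMinRelIntensity mask-growth intensity gate (see
#'   [SegmentationConfig-class]).
#' @return A validated [SegmentationConfig-class].
#' @examples
#' cfg <- segmentationConfig(minAreaPx = 200)
#' @export
segmentationConfig <- function(thresholdStartQuantile = 0.995,
                               thresholdDecayFactor = 0.9,
                               thresholdFloorQuantile = 0.5,
                               minAreaPx = 500,
                               maxAreaPx = 15000,
                               minSolidity = 0.90,
                               excludeBorder = TRUE,
                               smoothingSigmaPx = 1.0,
                               growMinRelIntensity = 0.3) {
  new("SegmentationConfig",
    thresholdStartQuantile = thresholdStartQuantile,
    thresholdDecayFactor = thresholdDecayFactor,
    thresholdFloorQuantile = thresholdFloorQuantile,
    minAreaPx = minAreaPx, maxAreaPx = maxAreaPx,
    minSolidity = minSolidity, excludeBorder = excludeBorder,
    smoothingSigmaPx = smoothingSigmaPx,
    growMinRelIntensity = growMinRelIntensity)
}

setMethod("show", "SegmentationConfig", function(object) {
  cat(sprintf(
    "SegmentationConfig: thresholds q%.3f -> q%.3f (decay %.2f), area [%g, %g] px, solidity >= %.2f%s, sigma %.1f px\n",
    object@thresholdStartQuantile, object@thresholdFloorQuantile,
    object@thresholdDecayFactor, object@minAreaPx, object@maxAreaPx,
    object@minSolidity, if (object@excludeBorder) ", border excluded" else "",
    object@smoothingSigmaPx))
})

# Build a NucleusMask from a pixel coordinate matrix, computing the derived
# statistics once.
newNucleusMask <- function(nucleusId, pixels) {
  pixels <- cbind(as.integer(pixels[, 1L]), as.integer(pixels[, 2L]))
  colnames(pixels) <- c("row", "col")
  new("NucleusMask",
    nucleusId = as.integer(nucleusId),
    pixels = pixels,
    areaPx = nrow(pixels),
    solidity = maskSolidity(pixels),
    centroid = c(mean(pixels[, 1L]), mean(pixels[, 2L])),
    bbox = c(min(pixels[, 1L]), min(pixels[, 2L]),
             max(pixels[, 1L]), max(pixels[, 2L])))
}

#' @describeIn segmentCascade accessors for a `NucleusMask`: id, area (px),
#'   solidity, centroid `(row, col)` and bounding box.
#' @param mask a [NucleusMask-class].
#' @export
nucleusId <- function(mask) mask@nucleusId

#' @rdname segmentCascade
#' @export
maskArea <- function(mask) mask@areaPx

#' @rdname segmentCascade
#' @export
maskCentroid <- function(mask) mask@centroid

#' @rdname segmentCascade
#' @export
maskPixels <- function(mask) mask@pixels

setMethod("show", "NucleusMask", function(object) {
  cat(sprintf("NucleusMask #%d: %d px, solidity %.3f, centroid (%.1f, %.1f)\n",
    object@nucleusId, object@areaPx, object@solidity,
    object@centroid[1L], object@centroid[2L]))
})

setMethod("show", "NucleusTrack", function(object) {
  cat(sprintf("NucleusTrack #%d: %d frame(s)%s, %d carried\n",
    object@nucleusId, length(object@frameIndex),
    if (is.na(object@lostAtFrame)) "" else sprintf(", lost at frame %d", object@lostAtFrame),
    sum(object@status == "carried")))
})

#' @describeIn trackNuclei `TRUE` if the track was lost before the end of the
#'   stack.
#' @param track a [NucleusTrack-class].
#' @export
isLost <- function(track) !is.na(track@lostAtFrame)

setMethod("show", "StripeFit", function(object) {
  if (object@ok)
    cat(sprintf("StripeFit: angle %g deg, D = %d px, P = %d px, width %g px, F = %.4f\n",
      object@angleDeg, object@dPx, object@pPx, object@widthPx, object@fValue))
  else cat("StripeFit: <failed>\n")
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig (%s): %d nuclei in %d x %d px, %d lines (gauge %d px, width %g px),\n  %d frames, motion sigma %g px, read noise %g, seed %d\n",
    object@mode, object@nNuclei, object@fieldSize[1L], object@fieldSize[2L],
    object@linesPerField, object@fieldSize[1L] %/% object@linesPerField,
    object@stripeWidthPx, length(object@timesMin), object@motionSigmaPx,
    object@readNoiseSd, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth (%s): %d nuclei, %d frames, gauge %d px, width %g px\n",
    object@mode, nrow(object@msTrue), ncol(object@msTrue),
    object@gaugePx, object@widthPx))
})

#' @describeIn renderScene programmed MS matrix (nuclei x frames) of a
#'   ground-truth object.
#' @param truth a [GroundTruth-class].
#' @export
msTrue <- function(truth) truth@msTrue

#' @describeIn renderScene per-frame integer label images of a ground-truth
#'   object.
#' @export
gtLabels <- function(truth) truth@labels
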