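#' @import methods
NULL

#' FrameStack: a timed sequence of 2D intensity frames
#'
#' Container for one field of view of a time-lapse acquisition. Frames are
#' numeric matrices indexed `[row, col]` (row 1 = top of the image), all of
#' identical dimension, with finite non-negative intensities. Times are in
#' minutes relative to micro-irradiation: the first frame is acquired at or
#' before t = 0, i.e. before the laser draws the stripes.
#'
#' @slot frames list of numeric matrices, one per time point.
#' @slot timesMin numeric, strictly increasing acquisition times in minutes;
#'   the first entry must be <= 0.
#' @slot pixelSizeUm physical pixel size in micrometres (informational; may
#'   be `NA`).
#' @slot channelLabel free-text channel description.
#'
#' @seealso [frameStack()], [readStack()]
#' @export
setClass("FrameStack",
  representation(
    frames = "list",
    timesMin = "numeric",
    pixelSizeUm = "numeric",
    channelLabel = "character"
  ),
  prototype(pixelSizeUm = NA_real_, channelLabel = "")
)

setValidity("FrameStack", function(object) {
  fr <- object@frames
  if (length(fr) == 0L) return("frames must contain at least one frame")
  if (!all(vapply(fr, function(f) is.matrix(f) && is.numeric(f), logical(1))))
    return("all frames must be numeric matrices")
  d <- dim(fr[[1L]])
  if (!all(vapply(fr, function(f) identical(dim(f), d), logical(1))))
    return("all frames must share identical dimensions")
  for (f in fr) {
    if (anyNA(f) || any(!is.finite(f))) return("frame intensities must be finite")
    if (any(f < 0)) return("frame intensities must be non-negative")
  }
  t <- object@timesMin
  if (length(t) != length(fr))
    return("timesMin must have one entry per frame")
  if (anyNA(t) || any(!is.finite(t))) return("timesMin must be finite")
  if (length(t) > 1L && any(diff(t) <= 0))
    return("timesMin must be strictly increasing")
  if (t[1L] > 0)
    return("first frame must be acquired at or before micro-irradiation (t <= 0)")
  TRUE
})

#' SegmentationConfig: tunables for the threshold-cascade nucleus finder
#'
#' The cascade thresholds the (optionally smoothed) image at a decreasing
#' sequence of levels: the starting level is the `thresholdStartQuantile`
#' quantile of the image, each subsequent level is the previous one multiplied
#' by `thresholdDecayFactor`, and the schedule stops at the
#' `thresholdFloorQuantile` quantile. Connected components passing the size
#' and solidity gates become nuclei; at lower levels masks may grow within
#' the gates but never merge.
#'
#' @slot thresholdStartQuantile first threshold, as an image quantile (default 0.995).
#' @slot thresholdDecayFactor multiplicative decay of the threshold value, in (0, 1)
#'   (default 0.9).
#' @slot thresholdFloorQuantile quantile giving the lowest threshold (default 0.5).
#' @slot minAreaPx,maxAreaPx accepted nucleus area range in pixels
#'   (defaults 500 and 15000, suited to a 40x objective at zoom 0.6).
#' @slot minSolidity minimum area / convex-hull-area ratio (default 0.90);
#'   rejects concave debris and partial rings.
#' @slot excludeBorder drop masks touching the frame border (default `TRUE`);
#'   clipped nuclei bias the striation measure.
#' @slot smoothingSigmaPx Gaussian pre-smoothing sigma in pixels (default 1;
#'   0 disables smoothing, appropriate for noise-free data).
#' @slot growMinRelIntensity growth gate: a mask grows to a lower-level
#'   component only if the mean raw intensity of the gained pixels is at
#'   least this fraction of the current mask's mean (default 0.3); keeps
#'   masks from accreting background halo. 0 disables the gate.
#'
#' @seealso [segmentationConfig()], [segmentCascade()]
#' @export
setClass("SegmentationConfig",
  representation(
    thresholdStartQuantile = "numeric",
    thresholdDecayFactor = "numeric",
    thresholdFloorQuantile = "numeric",
    minAreaPx = "numeric",
    maxAreaPx = "numeric",
    minSolidity = "numeric",
    excludeBorder = "logical",
    smoothingSigmaPx = "numeric",
    growMinRelIntensity = "numeric"
  ),
  prototype(
    thresholdStartQuantile = 0.995,
    thresholdDecayFactor = 0.9,
    thresholdFloorQuantile = 0.5,
    minAreaPx = 500,
    maxAreaPx = 15000,
    minSolidity = 0.90,
    excludeBorder = TRUE,
    smoothingSigmaPx = 1.0,
    growMinRelIntensity = 0.3
  )
)

setValidity("SegmentationConfig", function(object) {
  s <- object@thresholdStartQuantile
  f <- object@thresholdFloorQuantile
  d <- object@thresholdDecayFactor
  if (!(f > 0 && f <= s && s <= 1))
    return("quantiles must satisfy 0 < floor <= start <= 1")
  if (!(d > 0 && d < 1)) return("thresholdDecayFactor must be in (0, 1)")
  if (!(object@minAreaPx > 0 && object@minAreaPx < object@maxAreaPx))
    return("need 0 < minAreaPx < maxAreaPx")
  if (!(object@minSolidity > 0 && object@minSolidity <= 1))
    return("minSolidity must be in (0, 1]")
  if (object@smoothingSigmaPx < 0) return("smoothingSigmaPx must be >= 0")
  if (object@growMinRelIntensity < 0 || object@growMinRelIntensity > 1)
    return("growMinRelIntensity must be in [0, 1]")
  TRUE
})

#' NucleusMask: one segmented nucleus in one frame
#'
#' Pixels are stored as a two-column integer matrix of `(row, col)`
#' coordinates (1-based). Derived statistics (area, centroid, bounding box,
#' solidity) are computed once at construction.
#'
#' @slot nucleusId integer label.
#' @slot pixels integer matrix with columns `row`, `col`.
#' @slot areaPx number of pixels.
#' @slot solidity area divided by convex-hull area, in (0, 1].
#' @slot centroid numeric `(row, col)` of the pixel centroid.
#' @slot bbox integer `(minRow, minCol, maxRow, maxCol)`.
#'
#' @seealso [segmentCascade()]
#' @export
setClass("NucleusMask",
  representation(
    nucleusId = "integer",
    pixels = "matrix",
    areaPx = "integer",
    solidity = "numeric",
    centroid = "numeric",
    bbox = "integer"
  )
)

setValidity("NucleusMask", function(object) {
  p <- object@pixels
  if (!is.matrix(p) || ncol(p) != 2L || nrow(p) == 0L)
    return("pixels must be a non-empty two-column matrix")
  if (object@areaPx != nrow(p)) return("areaPx must equal the number of pixels")
  if (!(object@solidity > 0 && object@solidity <= 1 + 1e-9))
    return("solidity must be in (0, 1]")
  TRUE
})

#' NucleusTrack: one nucleus followed across frames
#'
#' A track starts at the first frame and carries one mask per frame until the
#' nucleus is lost; lost tracks are never resurrected and contribute no
#' further records. Per-frame status is `"tracked"` when the nucleus was
#' re-acquired by local segmentation and `"carried"` when the previous mask
#' was carried forward rigidly through a transient detection failure.
#'
#' @slot nucleusId integer label, matching the frame-1 mask.
#' @slot frameIndex integer vector of frames with an entry (strictly
#'   increasing, starting at 1).
#' @slot masks list of [NucleusMask-class], parallel to `frameIndex`.
#' @slot status character vector, `"tracked"` or `"carried"`, parallel to
#'   `frameIndex`.
#' @slot lostAtFrame frame at which the track was declared lost
#'   (`NA` if followed to the end).
#'
#' @seealso [trackNuclei()]
#' @export
setClass("NucleusTrack",
  representation(
    nucleusId = "integer",
    frameIndex = "integer",
    masks = "list",
    status = "character",
    lostAtFrame = "integer"
  ),
  prototype(lostAtFrame = NA_integer_)
)

setValidity("NucleusTrack", function(object) {
  n <- length(object@frameIndex)
  if (length(object@masks) != n || length(object@status) != n)
    return("frameIndex, masks and status must have equal length")
  if (n == 0L) return("a track must have at least one frame entry")
  if (object@frameIndex[1L] != 1L) return("a track must start at frame 1")
  if (n > 1L && any(diff(object@frameIndex) <= 0))
    return("frameIndex must be strictly increasing")
  if (!all(object@status %in% c("tracked", "carried")))
    return("status entries must be 'tracked' or 'carried'")
  TRUE
})

#' StripeFit: fitted stripe geometry inside one nucleus
#'
#' Describes the collinear stripe pattern of a rotated nucleus image: the
#' rotation applied so stripes run vertically, the gauge `D` (distance between
#' stripe centers, integer pixels), the offset `P` of the first stripe center
#' from the rightmost mask column, and the user-defined stripe width (a
#' property of the scanning hardware; it is not fitted). `fValue` is the ratio
#' of the mean intensity inside the stripe bands to the mean intensity over
#' the whole nucleus at the optimum; it equals 1 for a perfectly homogeneous
#' nucleus.
#'
#' @slot angleDeg rotation (degrees, on the search grid) applied so stripes
#'   are vertical.
#' @slot dPx integer gauge in pixels.
#' @slot pPx integer offset in pixels (>= 0).
#' @slot widthPx stripe width in pixels (user constant).
#' @slot fValue objective value at the optimum.
#' @slot ok `FALSE` when no valid (D, P) candidate produced a non-empty stripe
#'   region (fit failure; downstream records are flagged).
#'
#' @seealso [fitStripes()], [stripeObjective()]
#' @export
setClass("StripeFit",
  representation(
    angleDeg = "numeric",
    dPx = "integer",
    pPx = "integer",
    widthPx = "numeric",
    fValue = "numeric",
    ok = "logical"
  ),
  prototype(ok = TRUE)
)

setValidity("StripeFit", function(object) {
  if (object@ok) {
    if (object@widthPx >= object@dPx) return("widthPx must be smaller than dPx")
    if (object@pPx < 0L) return("pPx must be >= 0")
    if (!is.na(object@fValue) && object@fValue < 0)
      return("fValue must be >= 0")
  }
  TRUE
})

#' SceneConfig: parameters of the synthetic striping scene generator
#'
#' Defines a seeded synthetic field of elliptical nuclei exposed to a
#' horizontal collinear stripe pattern, with programmed recruitment (DDR) or
#' bleaching/recovery (FRAP) kinetics, nucleus motion and detector noise.
#' Baseline intensities are drawn log-uniformly over a configurable fold range
#' (default 10x) to emulate the large inter-nucleus intensity variance of
#' live-cell reporter systems. The implied stripe gauge is
#' `fieldSize[1] / linesPerField` and must be an integer.
#'
#' @slot fieldSize integer `(rows, cols)` of the field (default 512 x 512).
#' @slot nNuclei number of nuclei to place (default 20).
#' @slot axesRangePx range of the ellipse semi-major axis in pixels
#'   (default 18-26).
#' @slot axisRatioRange range of minor/major axis ratio (default 0.7-1).
#' @slot baselineLow lowest nucleus baseline intensity (default 500, on a
#'   16-bit-like scale).
#' @slot baselineFold fold range of the log-uniform baseline draw (default 10).
#' @slot background additive background level (default 100).
#' @slot readNoiseSd Gaussian read-noise sigma (default 150, giving a
#'   signal-to-noise ratio of about 10 at the geometric-median baseline).
#' @slot shotNoise add Poisson shot noise on the pre-noise intensity
#'   (default `FALSE`).
#' @slot motionSigmaPx per-frame isotropic Gaussian step sigma of nucleus
#'   centers in pixels (default 0).
#' @slot linesPerField number of stripes drawn across the field (default 32,
#'   the low-resolution scan setting that yields 1-2 stripes per nucleus).
#' @slot stripeWidthPx stripe width in pixels (default 5).
#' @slot stripeOffsetPx row of the first stripe center (default half a gauge).
#' @slot mode `"DDR"` (recruitment) or `"FRAP"` (bleach and recovery).
#' @slot ampRange per-nucleus amplitude range: peak MS for DDR (default
#'   0.8-1.4), minimum (negative) MS for FRAP.
#' @slot tauRiseMin,tauDecayMin DDR rise and decay time constants in minutes
#'   (defaults 5 and 60).
#' @slot tauRecoveryMin FRAP recovery time constant in minutes (default 30).
#' @slot timesMin frame acquisition times in minutes (first must be <= 0).
#' @slot seed RNG seed; a fixed seed yields bit-identical scenes.
#'
#' @seealso [sceneConfig()], [renderScene()], [kineticModel()]
#' @export
setClass("SceneConfig",
  representation(
    fieldSize = "integer",
    nNuclei = "integer",
    axesRangePx = "numeric",
    axisRatioRange = "numeric",
    baselineLow = "numeric",
    baselineFold = "numeric",
    background = "numeric",
    readNoiseSd = "numeric",
    shotNoise = "logical",
    motionSigmaPx = "numeric",
    linesPerField = "integer",
    stripeWidthPx = "numeric",
    stripeOffsetPx = "numeric",
    mode = "character",
    ampRange = "numeric",
    tauRiseMin = "numeric",
    tauDecayMin = "numeric",
    tauRecoveryMin = "numeric",
    timesMin = "numeric",
    seed = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  fs <- object@fieldSize
  if (length(fs) != 2L || any(fs < 32L)) return("fieldSize must be two values >= 32")
  if (fs[1L] %% object@linesPerField != 0L)
    return("fieldSize[1] must be divisible by linesPerField (integer gauge)")
  gauge <- fs[1L] / object@linesPerField
  if (object@stripeWidthPx >= gauge) return("stripe width must be smaller than the gauge")
  if (object@nNuclei < 1L) return("nNuclei must be >= 1")
  if (!(object@mode %in% c("DDR", "FRAP"))) return("mode must be 'DDR' or 'FRAP'")
  if (object@baselineFold < 1) return("baselineFold must be >= 1")
  if (object@readNoiseSd < 0 || object@motionSigmaPx < 0)
    return("noise and motion sigmas must be >= 0")
  if (object@mode == "DDR" && any(object@ampRange <= 0))
    return("DDR amplitudes must be positive")
  if (object@mode == "FRAP" && any(object@ampRange >= 0 | object@ampRange <= -1))
    return("FRAP amplitudes must be in (-1, 0)")
  if (any(c(object@tauRiseMin, object@tauDecayMin, object@tauRecoveryMin) <= 0))
    return("time constants must be positive")
  t <- object@timesMin
  if (length(t) < 2L || any(diff(t) <= 0) || t[1L] > 0)
    return("timesMin must be strictly increasing with first time <= 0")
  TRUE
})

#' GroundTruth: rendered scene truth for validating the pipeline
#'
#' @slot labels list of integer label matrices, one per frame (0 = background).
#' @slot trajectories data.frame with columns `frame`, `nucleus_id`, `row`,
#'   `col` (true centers).
#' @slot msTrue numeric matrix, nuclei x frames, of programmed MS values.
#' @slot stripeCenterRows integer rows of the stripe centers in the field.
#' @slot gaugePx,widthPx stripe geometry.
#' @slot kinetics data.frame of per-nucleus kinetic parameters.
#' @slot mode `"DDR"` or `"FRAP"`.
#'
#' @seealso [renderScene()]
#' @export
setClass("GroundTruth",
  representation(
    labels = "list",
    trajectories = "data.frame",
    msTrue = "matrix",
    stripeCenterRows = "integer",
    gaugePx = "integer",
    widthPx = "numeric",
    kinetics = "data.frame",
    mode = "character"
  )
)
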