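#' Segment nuclei with a cascade of decreasing thresholds
#'
#' Global single-threshold methods (e.g. Otsu) fail on live-cell reporter
#' images because baseline intensity varies by an order of magnitude between
#' nuclei: any single level either merges bright nuclei with background
#' structure or misses dim ones entirely. The cascade instead thresholds the
#' (optionally Gaussian-smoothed) frame at a decreasing sequence of levels.
#' At each level, 4-connected components are hole-filled and gated on area
#' and solidity; passing components are accepted as nuclei. At lower levels a
#' nucleus mask is allowed to grow to the enclosing component as long as the
#' gates still hold -- this recovers the dim rim and inter-stripe pixels of
#' striped nuclei -- but a component that would merge two accepted nuclei is
#' ignored, so identities never fuse. The procedure is deterministic for a
#' fixed frame and configuration.
#'
#' @param frame numeric matrix of finite, non-negative intensities.
#' @param cfg a [SegmentationConfig-class]; see [segmentationConfig()].
#' @return List of [NucleusMask-class] objects with disjoint pixel sets,
#'   labelled 1..n in acceptance order (threshold level, then raster order).
#'   An all-zero frame yields an empty list.
#' @examples
#' f <- matrix(0, 64, 64)
#' f[20:40, 20:40] <- 1000
#' segmentCascade(f, segmentationConfig(minAreaPx = 100, smoothingSigmaPx = 0))
#' @export
segmentCascade <- function(frame, cfg = segmentationConfig()) {
  if (!is.matrix(frame) || length(frame) == 0L) stop("frame must be a non-empty matrix")
  if (anyNA(frame) || any(!is.finite(frame)) || any(frame < 0))
    stop("frame must be finite and non-negative")
  validObject(cfg)
  if (all(frame == 0)) return(list())
  img <- if (cfg@smoothingSigmaPx > 0)
    as.matrix(EBImage::gblur(frame, sigma = cfg@smoothingSigmaPx))
  else frame
  thresholds <- thresholdSchedule(img, cfg)
  owner <- matrix(0L, nrow(img), ncol(img))   # pixel -> accepted nucleus id
  accepted <- list()
  for (th in thresholds) {
    bw <- img >= th
    lab <- EBImage::bwlabel(bw)
    lab <- as.matrix(EBImage::fillHull(lab))
    counts <- tabulate(lab[lab > 0L])
    for (id in which(counts >= cfg@minAreaPx & counts <= cfg@maxAreaPx)) {
      idx <- which(lab == id)
      owners <- unique(owner[idx])
      owners <- owners[owners > 0L]
      if (length(owners) > 1L) next          # would merge two accepted nuclei
      pix <- arrayInd(idx, dim(img))
      if (cfg@excludeBorder &&
          (min(pix[, 1L]) == 1L || min(pix[, 2L]) == 1L ||
           max(pix[, 1L]) == nrow(img) || max(pix[, 2L]) == ncol(img))) next
      if (maskSolidity(pix) < cfg@minSolidity) next
      if (length(owners) == 0L) {            # new nucleus, accepted at this level
        k <- length(accepted) + 1L
        accepted[[k]] <- pix
        owner[idx] <- k
      } else {
        # growth: lower levels recover the dim rim of the same nucleus, but
        # only while the gained pixels carry real signal (raw-intensity gate
        # against background-halo accretion)
        k <- owners
        curIdx <- which(owner == k)
        gain <- setdiff(idx, curIdx)
        if (length(gain) &&
            mean(frame[gain]) <
              cfg@growMinRelIntensity * mean(frame[curIdx])) next
        owner[curIdx] <- 0L
        accepted[[k]] <- pix
        owner[idx] <- k
      }
    }
  }
  # spans are judged on the smoothed image (robust for dim nuclei); halo
  # rows are peeled on raw medians (see refineMaskRows)
  bg <- stats::median(img)
  bgRaw <- stats::median(frame)
  refined <- lapply(accepted, function(pix)
    refineMaskRows(img, pix, bg, peel = cfg@smoothingSigmaPx > 0,
                   imgRaw = frame, bgRaw = bgRaw))
  lapply(seq_along(refined), function(i) newNucleusMask(i, refined[[i]]))
}

# Tighten a mask boundary row by row: within each image row (the stripe
# direction), the row is cut back to the contiguous span between its
# outermost crossings of the half-height between the local background and
# the row's own interior level (its median over the candidate pixels). The
# half-height of a blurred step edge sits at the true boundary, and doing it
# per row handles stripe and inter-stripe rows -- whose step heights differ
# -- alike; keeping the full span between the crossings avoids eroding
# noisy interiors. A refinement that would shrink the mask below half its
# size is rejected as degenerate.
refineMaskRows <- function(img, pix, bg, peel = FALSE, imgRaw = img,
                           bgRaw = bg) {
  rows <- sort(unique(pix[, 1L]))
  levels <- vapply(rows, function(r)
    stats::median(img[cbind(r, pix[pix[, 1L] == r, 2L])]), numeric(1))
  if (peel && length(rows) > 2L) {
    # peel blur-halo rows from the vertical extremes, judged on RAW medians:
    # a halo row is pure background in the raw image no matter how bright
    # the nucleus cap that feeds its smoothed values, while an interior dim
    # row (a bleached stripe) is never peeled
    rawLevels <- vapply(rows, function(r)
      stats::median(imgRaw[cbind(r, pix[pix[, 1L] == r, 2L])]), numeric(1))
    # median-filter the level profile so a single noise-fluke row cannot
    # rescue a block of halo rows
    if (length(rawLevels) >= 3L)
      rawLevels <- stats::runmed(rawLevels, 3L, endrule = "median")
    floorLevel <- bgRaw + 0.25 * (stats::median(rawLevels) - bgRaw)
    good <- which(rawLevels >= floorLevel)
    if (length(good)) {
      inside <- pix[, 1L] >= rows[min(good)] & pix[, 1L] <= rows[max(good)]
      pix <- pix[inside, , drop = FALSE]
      levels <- levels[min(good):max(good)]
      rows <- rows[min(good):max(good)]
    }
  }
  keep <- logical(nrow(pix))
  for (j in seq_along(rows)) {
    r <- rows[j]
    sel <- which(pix[, 1L] == r)
    ord <- order(pix[sel, 2L])
    sel <- sel[ord]
    cols <- pix[sel, 2L]
    vals <- img[cbind(r, cols)]
    level <- levels[j]
    if (level <= bg) { keep[sel] <- TRUE; next }
    span <- longestBridgedRun(vals >= bg + 0.5 * (level - bg))
    if (!is.null(span))
      keep[sel] <- seq_along(cols) >= span[1L] & seq_along(cols) <= span[2L]
  }
  if (sum(keep) < nrow(pix) / 2) return(pix)
  pix[keep, , drop = FALSE]
}

# Longest run of TRUE values, allowing interior gaps of up to `gap` FALSEs
# (noise dips); returns c(start, end) indices or NULL. Using the longest run
# instead of the outermost TRUEs avoids the extreme-value dilation bias of
# stray suprathreshold pixels beyond the real edge.
longestBridgedRun <- function(x, gap = 2L) {
  idx <- which(x)
  if (length(idx) == 0L) return(NULL)
  breaks <- which(diff(idx) > gap + 1L)
  starts <- idx[c(1L, breaks + 1L)]
  ends <- idx[c(breaks, length(idx))]
  k <- which.max(ends - starts)
  c(starts[k], ends[k])
}

# Decreasing threshold schedule: start at the start-quantile value and decay
# multiplicatively down to the floor-quantile value. A hard floor of 1e-4 of
# the start value keeps the schedule finite on zero-background images. When
# the start quantile lands on 0 (very sparse fields), quantiles of the
# positive pixels are used instead.
thresholdSchedule <- function(img, cfg) {
  t0 <- as.numeric(stats::quantile(img, cfg@thresholdStartQuantile, names = FALSE))
  tf <- as.numeric(stats::quantile(img, cfg@thresholdFloorQuantile, names = FALSE))
  if (t0 <= 0) {
    pos <- img[img > 0]
    t0 <- as.numeric(stats::quantile(pos, cfg@thresholdStartQuantile, names = FALSE))
    tf <- as.numeric(stats::quantile(pos, cfg@thresholdFloorQuantile, names = FALSE))
  }
  tf <- max(tf, t0 * 1e-4)
  n <- max(1L, ceiling(log(tf / t0) / log(cfg@thresholdDecayFactor)) + 1L)
  th <- t0 * cfg@thresholdDecayFactor^(seq_len(n) - 1L)
  th[th >= tf * (1 - 1e-12)]
}

#' Segment nuclei from a DNA (Hoechst) counterstain channel
#'
#' Fixed-sample variant: the tracking module is not used and nuclei are
#' recognized on the DNA-stain channel, whose per-nucleus signal is uniform
#' regardless of the striation in the signal channel. The contract is
#' identical to [segmentCascade()]; downstream, the Measure of Striation is
#' then computed on the signal channel inside these DNA-derived masks.
#'
#' @param dnaFrame numeric matrix of the DNA-channel intensities.
#' @inheritParams segmentCascade
#' @return List of [NucleusMask-class] objects positioned by the DNA channel.
#' @export
segmentHoechst <- function(dnaFrame, cfg = segmentationConfig()) {
  segmentCascade(dnaFrame, cfg)
}

# Render masks as an integer label image (used for QC overlays and tests).
labelImage <- function(masks, nrow, ncol) {
  lab <- matrix(0L, nrow, ncol)
  for (m in masks) lab[m@pixels] <- m@nucleusId
  lab
}
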