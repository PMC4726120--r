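#' Find the stripe orientation of a nucleus image by Radon transform
#'
#' Projects the mask-mean-subtracted intensities onto a 1-degree grid of
#' directions over `[0, 180)` and returns the angle at which the projection
#' is most concentrated (ties broken by the smallest angle). The mean
#' subtraction cancels the contribution of the nucleus shape itself, so an
#' elongated homogeneous nucleus does not bias the orientation: only periodic
#' intensity structure contributes. The image and mask are then rotated by
#' that angle so the stripes run vertically; multiples of 90 degrees are
#' rotated exactly (pure array permutation), other angles bilinearly for
#' intensities and nearest-neighbour for the mask. For a nucleus without
#' stripes all projections of the centred signal are near zero and the
#' returned angle is the deterministic tie-break (harmless: MS is near zero
#' for a homogeneous nucleus at any rotation).
#'
#' @param nucleusImage numeric matrix; the masked sub-image of one nucleus
#'   (pixels outside the mask must be zero).
#' @param mask logical matrix of the same dimension marking nucleus pixels.
#' @param anglesDeg angular search grid in degrees (default `0:179`).
#' @return List with `angleDeg` (the chosen grid angle), `image` and `mask`
#'   (both rotated so stripes are vertical).
#' @seealso [fitStripes()]
#' @export
rotateToVertical <- function(nucleusImage, mask, anglesDeg = 0:179) {
  if (!is.matrix(nucleusImage) || length(nucleusImage) == 0L) stop("empty image")
  if (!any(mask)) stop("empty mask")
  angle <- radonMaxAngle(nucleusImage, mask, anglesDeg)
  # rotating a pattern by a adds a to its Radon angle, so rotating by -angle
  # brings the peak direction to 0 degrees, i.e. stripes vertical
  rot <- rotateArrays(nucleusImage, mask, -angle)
  list(angleDeg = angle, image = rot$image, mask = rot$mask)
}

# Angle (degrees) at which the discrete Radon transform of the
# mask-mean-subtracted image is most peaked. Projections bin the pixel
# coordinate along direction (cos a, sin a) in (col, row) axes; parallel
# stripes concentrate the projection when that direction is the stripe
# normal. Peakedness is scored as the projection energy (sum of squared bin
# masses) averaged over four sub-pixel bin origins: on discretized data the
# single tallest bin is degenerate (whole families of angles tie on
# two-valued images, and the score depends on the arbitrary bin phase),
# whereas the origin-averaged energy is maximized exactly at alignment.
# Ties still break to the smallest angle.
radonMaxAngle <- function(img, mask, anglesDeg = 0:179,
                          binOrigins = c(0, 0.25, 0.5, 0.75)) {
  idx <- which(mask)
  vals <- img[idx] - mean(img[idx])
  rc <- arrayInd(idx, dim(img))
  y <- rc[, 1L] - mean(rc[, 1L])
  x <- rc[, 2L] - mean(rc[, 2L])
  th <- anglesDeg * pi / 180
  S <- cbind(x, y) %*% rbind(cos(th), sin(th))
  best <- -Inf
  bestAngle <- anglesDeg[1L]
  for (j in seq_along(anglesDeg)) {
    e <- 0
    for (o in binOrigins)
      e <- e + sum(rowsum(vals, round(S[, j] - o))^2)
    if (e > best) { best <- e; bestAngle <- anglesDeg[j] }
  }
  bestAngle
}

# Rotate image (bilinear) and mask (nearest-neighbour) by `angle` degrees so
# that structure along the radon-max direction becomes vertical. Multiples of
# 90 are exact array permutations.
rotateArrays <- function(img, mask, angle) {
  a <- angle %% 360
  if (a %% 90 == 0) {
    return(list(image = rotateExact(img, a),
                mask = rotateExact(mask, a)))
  }
  # EBImage::rotate on a [row, col] matrix turns the opposite way round from
  # rotateExact's convention, hence the sign flip.
  ri <- as.matrix(EBImage::rotate(img, -a, filter = "bilinear", bg.col = 0))
  rm_ <- as.matrix(EBImage::rotate(mask * 1, -a, filter = "none", bg.col = 0))
  list(image = ri, mask = rm_ >= 0.5)
}

# Stripe-band column membership. Stripe centers sit at columns
# xRight - P - k*D (xRight = rightmost mask column); the pattern is periodic
# across the whole field, so a column belongs to a band when its distance to
# the NEAREST center (any integer k) is at most width/2. F and MS are thus
# exactly periodic in P with period D.
stripeColumnSet <- function(cols, xRight, dPx, pPx, widthPx) {
  u <- (xRight - pPx) - cols
  dmod <- u %% dPx
  dist <- pmin(dmod, dPx - dmod)
  cols[dist <= widthPx / 2 + 1e-9]
}

#' Stripe-fit objective F(D, P)
#'
#' Ratio of the mean intensity inside the stripe bands (intersected with the
#' nucleus mask) to the mean intensity over the whole nucleus. `F = 1` for an
#' image that is constant on the mask; by convention `F = 1` when the
#' whole-mask mean is zero. Returns `NA` when no stripe column intersects the
#' mask (the candidate is excluded from fitting).
#'
#' @param rotatedImage numeric matrix with stripes vertical (outside-mask
#'   pixels zero).
#' @param mask logical matrix of nucleus pixels.
#' @param dPx integer gauge (> `widthPx`).
#' @param pPx integer offset (>= 0) of the first stripe center from the
#'   rightmost mask column.
#' @param widthPx stripe width (user constant).
#' @return The objective value, or `NA` for an empty stripe region.
#' @export
stripeObjective <- function(rotatedImage, mask, dPx, pPx, widthPx) {
  if (dPx <= widthPx) stop("dPx must exceed widthPx")
  cs <- maskColumnStats(rotatedImage, mask)
  fFromColumns(cs, dPx, pPx, widthPx)
}

# Per-column intensity sums and pixel counts over the mask, plus totals.
maskColumnStats <- function(img, mask) {
  cnt <- colSums(mask)
  s <- colSums(img * mask)
  keep <- which(cnt > 0)
  list(cols = keep, colInt = s[keep], colCnt = cnt[keep],
       totalInt = sum(s[keep]), totalCnt = sum(cnt[keep]),
       xRight = max(keep))
}

fFromColumns <- function(cs, dPx, pPx, widthPx) {
  sc <- stripeColumnSet(cs$cols, cs$xRight, dPx, pPx, widthPx)
  if (length(sc) == 0L) return(NA_real_)
  sel <- cs$cols %in% sc
  areaS <- sum(cs$colCnt[sel])
  if (areaS == 0) return(NA_real_)
  if (cs$totalInt == 0) return(1)
  (sum(cs$colInt[sel]) / areaS) / (cs$totalInt / cs$totalCnt)
}

#' Fit stripe gauge and offset by exhaustive grid search
#'
#' Evaluates the objective [stripeObjective()] at every integer gauge `D` in
#' `dRange` and every integer offset `P` within `pWindowPx` of the anchor
#' offset -- the offset that places a stripe center on the column where the
#' per-column sum of signal over the mask is maximal -- and returns the
#' argmax. Offsets are phases of the field-wide periodic band pattern and are
#' canonicalized into `[0, D)`. Although gauge and offset are known from the laser settings,
#' refitting is necessary because nuclei are elastic and move; ties are
#' broken toward the smallest `D`, then the smallest `P`, making the fit
#' deterministic.
#'
#' @inheritParams stripeObjective
#' @param widthPx stripe width in pixels (not fitted).
#' @param dRange integer `c(dMin, dMax)` gauge search range.
#' @param pWindowPx half-width of the offset search window around the anchor.
#' @param direction `"bright"` (recruitment: stripes brighter than the rest
#'   of the nucleus; F is maximized and the offset anchor is the column of
#'   maximal signal sum) or `"dark"` (bleaching: stripes dimmer; F is
#'   minimized and the anchor is the column of minimal mean intensity).
#'   Without the dark mode a bleached pattern would be fitted to the bright
#'   inter-stripe bands and the MS could never be negative.
#' @return A [StripeFit-class]; `ok = FALSE` when the grid is empty or no
#'   candidate yields a non-empty stripe region (e.g. mask narrower than the
#'   stripe width).
#' @examples
#' img <- matrix(1, 40, 40); img[, c(8:10, 20:22, 32:34)] <- 3
#' mask <- matrix(TRUE, 40, 40)
#' fitStripes(img, mask, widthPx = 3, dRange = c(8, 16), pWindowPx = 6)
#' @export
fitStripes <- function(rotatedImage, mask, widthPx, dRange, pWindowPx,
                       direction = c("bright", "dark")) {
  direction <- match.arg(direction)
  failed <- new("StripeFit", angleDeg = 0, dPx = 0L, pPx = 0L,
                widthPx = widthPx, fValue = NA_real_, ok = FALSE)
  if (!any(mask)) return(failed)
  cs <- maskColumnStats(rotatedImage, mask)
  dCand <- seq.int(max(ceiling(dRange[1L]), floor(widthPx) + 1L), floor(dRange[2L]))
  if (length(dCand) == 0L) return(failed)
  sgn <- if (direction == "bright") 1 else -1
  cStar <- if (direction == "bright") cs$cols[which.max(cs$colInt)]
    else cs$cols[which.min(cs$colInt / cs$colCnt)]
  pAnchor <- cs$xRight - cStar
  pRaw <- seq.int(pAnchor - ceiling(pWindowPx), pAnchor + ceiling(pWindowPx))
  bestF <- -Inf; bestD <- NA_integer_; bestP <- NA_integer_
  for (D in dCand) {
    # offsets are phases: canonicalize the window into [0, D) and dedupe
    pCand <- sort(unique(pRaw %% D))
    for (P in pCand) {
      f <- fFromColumns(cs, D, P, widthPx)
      if (!is.na(f) && sgn * f > bestF) { bestF <- sgn * f; bestD <- D; bestP <- P }
    }
  }
  if (!is.finite(bestF)) return(failed)
  new("StripeFit", angleDeg = 0, dPx = as.integer(bestD), pPx = as.integer(bestP),
      widthPx = widthPx, fValue = sgn * bestF, ok = TRUE)
}

#' Compute the Measure of Striation for one nucleus at one time point
#'
#' The MS is the relative excess signal integrated density (SID) inside the
#' stripes: `MS = (J_meas - J_expt) / J_expt`, where `J_meas` is the SID over
#' the stripe bands intersected with the mask and `J_expt` is the SID those
#' bands would hold if the nucleus were perfectly homogeneous,
#' `J_expt = totalSID * stripeArea / maskArea`. The baseline is zero (no
#' excess signal in the stripes), recruitment gives positive MS, bleaching
#' negative MS (bounded below by -1), and multiplying every pixel by any
#' positive constant leaves MS unchanged -- the measure is independent of the
#' total SID of the nucleus, which varies greatly between cells.
#'
#' @param rotatedImage numeric matrix with stripes vertical.
#' @param mask logical matrix of nucleus pixels.
#' @param fit a [StripeFit-class] for this mask.
#' @return One-row data.frame with `ms`, `j_meas`, `j_expt`, `stripe_D`,
#'   `stripe_P`, `angle_deg`, `f_value`, `flagged`. Records with a failed fit
#'   or `J_expt = 0` (all-zero nucleus) are flagged with `ms = NA`.
#' @export
computeMS <- function(rotatedImage, mask, fit) {
  if (!fit@ok) {
    return(data.frame(ms = NA_real_, j_meas = NA_real_, j_expt = NA_real_,
                      stripe_D = NA_integer_, stripe_P = NA_integer_,
                      angle_deg = fit@angleDeg, f_value = NA_real_,
                      flagged = TRUE))
  }
  cs <- maskColumnStats(rotatedImage, mask)
  sc <- stripeColumnSet(cs$cols, cs$xRight, fit@dPx, fit@pPx, fit@widthPx)
  sel <- cs$cols %in% sc
  jMeas <- sum(cs$colInt[sel])
  areaS <- sum(cs$colCnt[sel])
  jExpt <- cs$totalInt * areaS / cs$totalCnt
  flagged <- jExpt <= 0
  data.frame(
    ms = if (flagged) NA_real_ else (jMeas - jExpt) / jExpt,
    j_meas = jMeas, j_expt = jExpt,
    stripe_D = fit@dPx, stripe_P = fit@pPx,
    angle_deg = fit@angleDeg, f_value = fit@fValue,
    flagged = flagged)
}

#' Measure-of-Striation time series for one tracked nucleus
#'
#' For every frame of the track, the nucleus sub-image is cut out, rotated to
#' vertical stripes, the stripe geometry is refitted and the MS computed.
#' Refitting every frame is the default and the point of the optimization
#' step: with a frozen frame-1 geometry the MS would drift downward as the
#' nucleus moves and deforms, creating a false apparent relaxation (see
#' [frozenFitSeries()] for the diagnostic that demonstrates this).
#'
#' @param track a [NucleusTrack-class].
#' @param stack the [FrameStack-class] the track was built on.
#' @param widthPx stripe width in pixels.
#' @param dRange integer gauge search range, e.g. from [defaultDRange()].
#' @param pWindowPx offset search half-window.
#' @param direction `"bright"` (recruitment) or `"dark"` (bleaching); see
#'   [fitStripes()].
#' @param anglesDeg angular grid for the rotation search.
#' @return data.frame with one row per tracked frame: `nucleus_id`,
#'   `frame`, `time_min`, and the [computeMS()] columns, ordered by time.
#'   Rows with failed fits, and rows measured on carried-forward (stale)
#'   masks, are flagged and excluded from curve building.
#' @export
msSeries <- function(track, stack, widthPx, dRange, pWindowPx,
                     direction = c("bright", "dark"), anglesDeg = 0:179) {
  direction <- match.arg(direction)
  rows <- lapply(seq_along(track@frameIndex), function(k) {
    f <- track@frameIndex[k]
    m <- track@masks[[k]]
    cut <- cutNucleus(getFrame(stack, f), m)
    rv <- rotateToVertical(cut$image, cut$mask, anglesDeg)
    fit <- fitStripes(rv$image, rv$mask, widthPx, dRange, pWindowPx, direction)
    fit@angleDeg <- rv$angleDeg
    rec <- computeMS(rv$image, rv$mask, fit)
    # a carried-forward mask sits at the stale position of the previous
    # frame; its MS is unreliable and is flagged out of curve building
    rec$flagged <- rec$flagged | track@status[k] == "carried"
    cbind(data.frame(nucleus_id = track@nucleusId, frame = f,
                     time_min = timesMin(stack)[f]), rec)
  })
  do.call(rbind, rows)
}

# Masked sub-image of one nucleus: crop to the bounding box (1 px pad) and
# zero everything outside the mask.
cutNucleus <- function(frame, mask) {
  bb <- mask@bbox
  r1 <- max(1L, bb[1L] - 1L); c1 <- max(1L, bb[2L] - 1L)
  r2 <- min(nrow(frame), bb[3L] + 1L); c2 <- min(ncol(frame), bb[4L] + 1L)
  sub <- frame[r1:r2, c1:c2, drop = FALSE]
  mm <- matrix(FALSE, r2 - r1 + 1L, c2 - c1 + 1L)
  mm[cbind(mask@pixels[, 1L] - r1 + 1L, mask@pixels[, 2L] - c1 + 1L)] <- TRUE
  sub[!mm] <- 0
  list(image = sub, mask = mm)
}

#' Diagnostic: MS series with the frame-1 stripe geometry frozen
#'
#' Fits the stripe geometry once on the first frame and then evaluates the MS
#' of every later frame against those fixed stripe bands held at their
#' absolute frame-1 positions (the whole field is rotated by the frame-1
#' angle so band positions are comparable across frames). As the nucleus
#' moves, the fixed bands drift out of register with the true stripes and the
#' MS decays even when the underlying striation is constant -- the systematic
#' error that per-frame refitting ([msSeries()]) exists to remove.
#'
#' @inheritParams msSeries
#' @return data.frame like [msSeries()] (without fit columns refreshed per
#'   frame; `stripe_D`/`stripe_P` are the frozen values).
#' @export
frozenFitSeries <- function(track, stack, widthPx, dRange, pWindowPx,
                            anglesDeg = 0:179) {
  # frame-1 fit in full-field coordinates
  m1 <- track@masks[[1L]]
  frame1 <- getFrame(stack, 1L)
  full1 <- frame1
  fullMask1 <- pixelsToMatrix(m1@pixels, nrow(frame1), ncol(frame1))
  full1[!fullMask1] <- 0
  angle <- radonMaxAngle(full1, fullMask1, anglesDeg)
  rot1 <- rotateArrays(full1, fullMask1, -angle)
  fit <- fitStripes(rot1$image, rot1$mask, widthPx, dRange, pWindowPx)
  if (!fit@ok) stop("frozen-fit diagnostic: frame-1 fit failed")
  cs1 <- maskColumnStats(rot1$image, rot1$mask)
  absCols <- seq_len(ncol(rot1$mask))
  frozenCols <- stripeColumnSet(absCols, cs1$xRight, fit@dPx, fit@pPx, widthPx)

  rows <- lapply(seq_along(track@frameIndex), function(k) {
    f <- track@frameIndex[k]
    m <- track@masks[[k]]
    frame <- getFrame(stack, f)
    fullMask <- pixelsToMatrix(m@pixels, nrow(frame), ncol(frame))
    img <- frame; img[!fullMask] <- 0
    rot <- rotateArrays(img, fullMask, -angle)
    cnt <- colSums(rot$mask)
    s <- colSums(rot$image * rot$mask)
    sel <- intersect(frozenCols, which(cnt > 0))
    jMeas <- sum(s[sel]); areaS <- sum(cnt[sel])
    jExpt <- sum(s) * areaS / sum(cnt)
    data.frame(nucleus_id = track@nucleusId, frame = f,
               time_min = timesMin(stack)[f],
               ms = if (jExpt > 0) (jMeas - jExpt) / jExpt else NA_real_,
               j_meas = jMeas, j_expt = jExpt,
               stripe_D = fit@dPx, stripe_P = fit@pPx,
               angle_deg = angle, f_value = fit@fValue,
               flagged = jExpt <= 0)
  })
  do.call(rbind, rows)
}

#' Default gauge search range and offset window from the acquisition setting
#'
#' The nominal gauge is the field height divided by the number of scan lines
#' (e.g. 512 px / 32 lines = 16 px). The search range spans 0.5x to 1.5x the
#' nominal gauge and the offset window half a nominal gauge, which covers a
#' full period of offsets.
#'
#' @param fieldRows image height in pixels.
#' @param linesPerField number of stripes drawn across the field.
#' @return `defaultDRange`: integer `c(dMin, dMax)`; `defaultPWindow`: integer
#'   half-window in pixels.
#' @export
defaultDRange <- function(fieldRows, linesPerField) {
  dNom <- fieldRows / linesPerField
  c(max(2L, floor(0.5 * dNom)), ceiling(1.5 * dNom))
}

#' @rdname defaultDRange
#' @export
defaultPWindow <- function(fieldRows, linesPerField) {
  ceiling(fieldRows / linesPerField / 2)
}
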