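# Shared fixtures: all synthetic, generated in code at test time.

# Analysis configuration for noise-free scenes: no smoothing or stripe
# bridging is needed (or wanted) when there is no noise.
noiselessConfig <- function(mode = "live_ddr", linesPerField = 32L) {
  analysisConfig(mode, linesPerField = linesPerField,
                 segmentation = segmentationConfig(smoothingSigmaPx = 0),
                 trackingBridgeSigmaPx = 0)
}

# Map each track to its ground-truth nucleus by majority overlap in frame 1
# and return per-record MS errors against the programmed values.
closureErrors <- function(scene, result) {
  lab <- gtLabels(scene$truth)[[1L]]
  out <- NULL
  for (tr in result$tracks) {
    gid <- as.integer(names(which.max(table(lab[maskPixels(tr@masks[[1L]])]))))
    sub <- result$ms[result$ms$nucleus_id == tr@nucleusId & !result$ms$flagged, ]
    out <- rbind(out, data.frame(
      gt_id = gid, frame = sub$frame,
      err = sub$ms - msTrue(scene$truth)[gid, sub$frame]))
  }
  out
}

# Majority-overlap assignment of every track to a ground-truth trajectory,
# frame by frame; returns a matrix tracks x frames of gt ids (NA when the
# track has no entry for that frame).
trackAssignments <- function(scene, tracks) {
  nT <- length(gtLabels(scene$truth))
  sapply(seq_len(nT), function(f) {
    lab <- gtLabels(scene$truth)[[f]]
    vapply(tracks, function(tr) {
      k <- match(f, tr@frameIndex)
      if (is.na(k)) return(NA_integer_)
      as.integer(names(which.max(table(lab[maskPixels(tr@masks[[k]])]))))
    }, integer(1))
  })
}

# A filled circular mask (logical matrix).
circleMask <- function(size, radius = size %/% 2 - 3) {
  ctr <- (size + 1) / 2
  outer(seq_len(size), seq_len(size),
        function(r, c) (r - ctr)^2 + (c - ctr)^2 <= radius^2)
}

# Vertical-striped image on a mask: bands of `bright` on `bg`, centers at
# columns xRight - P - k*D (periodic), band half-width floor(w/2).
stripedImage <- function(mask, dPx, pPx, widthPx, bright = 3, bg = 1) {
  cols <- which(colSums(mask) > 0)
  xR <- max(cols)
  u <- (xR - pPx) - seq_len(ncol(mask))
  dmod <- u %% dPx
  inBand <- pmin(dmod, dPx - dmod) <= widthPx / 2 + 1e-9
  img <- matrix(0, nrow(mask), ncol(mask))
  img[mask] <- bg
  img[mask & matrix(inBand, nrow(mask), ncol(mask), byrow = TRUE)] <- bright
  img
}

# Independently coded exhaustive F(D, P) grid search (the oracle for the
# fitter): brute-force pixel sums for every candidate, same anchor and
# tie-break rules, fresh code path.
oracleFitStripes <- function(img, mask, widthPx, dRange, pWindowPx,
                             direction = "bright") {
  fOf <- function(D, P) {
    cols <- which(colSums(mask) > 0)
    xR <- max(cols)
    centers <- xR - P - (-200:200) * D
    inBand <- vapply(seq_len(ncol(mask)), function(cc)
      any(abs(cc - centers) <= widthPx / 2 + 1e-9), logical(1))
    region <- mask & matrix(inBand, nrow(mask), ncol(mask), byrow = TRUE)
    if (!any(region)) return(NA_real_)
    if (mean(img[mask]) == 0) return(1)
    mean(img[region]) / mean(img[mask])
  }
  cnt <- colSums(mask)
  cols <- which(cnt > 0)
  colInt <- colSums(img * mask)[cols]
  cStar <- if (direction == "bright") cols[which.max(colInt)]
    else cols[which.min(colInt / cnt[cols])]
  pAnchor <- max(cols) - cStar
  sgn <- if (direction == "bright") 1 else -1
  best <- -Inf; bestD <- NA; bestP <- NA
  for (D in seq.int(max(dRange[1], floor(widthPx) + 1), dRange[2])) {
    for (P in sort(unique(seq.int(pAnchor - pWindowPx, pAnchor + pWindowPx) %% D))) {
      f <- fOf(D, P)
      if (!is.na(f) && sgn * f > best) { best <- sgn * f; bestD <- D; bestP <- P }
    }
  }
  list(dPx = bestD, pPx = bestP, fValue = sgn * best)
}
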