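#' Track nuclei across frames by vicinity search
#'
#' After micro-irradiation, the signal between the stripes of a nucleus can
#' fall toward background (strong recruitment drains the inter-stripe pool;
#' bleaching dims the stripes themselves), making striped nuclei invisible
#' to any whole-frame thresholding. Identity is therefore maintained by
#' local re-segmentation anchored to each track:
#'
#' 1. the previous mask's bounding box, dilated by `searchRadiusPx`, is cut
#'    out of the current frame;
#' 2. the crop is smoothed with `bridgeSigmaPx` (about a quarter of the
#'    stripe gauge), which bridges the periodic stripe modulation so the
#'    whole nucleus reappears as one component;
#' 3. the crop is thresholded halfway between the local background (crop
#'    median) and the track's own intensity level (lower quartile of the
#'    smoothed crop at the previous mask position) -- the half-height of a
#'    blurred step edge sits at the true boundary, so the mask is
#'    approximately unbiased;
#' 4. hole-filled components are gated on area and solidity, and the
#'    candidate whose centroid is nearest to the previous centroid (within
#'    `searchRadiusPx`) is accepted.
#'
#' The whole-frame cascade is deliberately not reused here: its
#' high-threshold levels would fragment a striped nucleus into inter-stripe
#' slabs, whereas inside a small crop dominated by one nucleus a single
#' track-anchored threshold suffices. Conflicts (two tracks claiming
#' overlapping pixels) are resolved globally: the track with the nearer
#' centroid wins (lower id on ties) and the loser falls back to its
#' next-best candidate or carries its previous mask forward rigidly. After
#' `maxCarry` consecutive carried frames without re-acquisition the track is
#' marked lost and contributes nothing further (no resurrection). The result
#' is deterministic for fixed input.
#'
#' @param stack a [FrameStack-class].
#' @param initial list of [NucleusMask-class] from the first frame (e.g. from
#'   [segmentCascade()] on frame 1, the pre-irradiation image).
#' @param searchRadiusPx search radius in pixels (default 25, a generous
#'   bound on inter-frame nuclear movement at 40x).
#' @param cfg [SegmentationConfig-class]; supplies the area and solidity
#'   gates for local candidates.
#' @param maxCarry maximum consecutive carried-forward frames before a track
#'   is lost (default 2).
#' @param bridgeSigmaPx Gaussian sigma (pixels) used to bridge the stripe
#'   modulation before local thresholding (default 4, suited to a 16 px
#'   gauge; 0 disables bridging, appropriate for noise-free data).
#' @return List of [NucleusTrack-class], one per initial mask. In any frame
#'   no pixel is claimed by two tracks.
#' @seealso [msSeries()]
#' @export
trackNuclei <- function(stack, initial, searchRadiusPx = 25,
                        cfg = segmentationConfig(), maxCarry = 2L,
                        bridgeSigmaPx = 4) {
  if (!is(stack, "FrameStack")) stop("stack must be a FrameStack")
  if (length(initial) == 0L) stop("no initial masks (frame-1 segmentation empty)")
  if (searchRadiusPx <= 0) stop("searchRadiusPx must be > 0")
  nT <- nFrames(stack)
  d <- dim(getFrame(stack, 1L))

  n <- length(initial)
  st <- lapply(seq_len(n), function(i) list(
    id = initial[[i]]@nucleusId,
    frames = 1L, masks = list(initial[[i]]), status = "tracked",
    carry = 0L, alive = TRUE, lostAt = NA_integer_))

  for (f in seq_len(nT)[-1L]) {
    frame <- getFrame(stack, f)
    aliveIdx <- which(vapply(st, `[[`, logical(1), "alive"))
    if (length(aliveIdx) == 0L) break
    # candidate masks per live track, sorted by centroid distance
    cands <- vector("list", n)
    for (i in aliveIdx) {
      prev <- st[[i]]$masks[[length(st[[i]]$masks)]]
      bb <- prev@bbox
      r1 <- max(1L, bb[1L] - ceiling(searchRadiusPx))
      c1 <- max(1L, bb[2L] - ceiling(searchRadiusPx))
      r2 <- min(d[1L], bb[3L] + ceiling(searchRadiusPx))
      c2 <- min(d[2L], bb[4L] + ceiling(searchRadiusPx))
      sub <- frame[r1:r2, c1:c2, drop = FALSE]
      prevCrop <- cbind(prev@pixels[, 1L] - r1 + 1L, prev@pixels[, 2L] - c1 + 1L)
      found <- localSegment(sub, cfg, prevCrop,
                            max(bridgeSigmaPx, cfg@smoothingSigmaPx))
      if (length(found)) {
        # plausibility: a candidate far off the previous size is a merged
        # blob (bridging can fuse near-touching nuclei) or a fragment
        aPrev <- prev@areaPx
        found <- Filter(function(p) nrow(p) >= 0.5 * aPrev &&
                                     nrow(p) <= 1.5 * aPrev, found)
      }
      if (length(found)) {
        cen <- prev@centroid
        shifted <- lapply(found, function(pix) {
          pix[, 1L] <- pix[, 1L] + r1 - 1L
          pix[, 2L] <- pix[, 2L] + c1 - 1L
          pix
        })
        dist <- vapply(shifted, function(p)
          sqrt((mean(p[, 1L]) - cen[1L])^2 + (mean(p[, 2L]) - cen[2L])^2),
          numeric(1))
        keep <- which(dist <= searchRadiusPx)
        cands[[i]] <- lapply(keep[order(dist[keep])], function(k)
          list(pixels = shifted[[k]], dist = dist[k]))
      }
    }

    claimed <- matrix(FALSE, d[1L], d[2L])
    pending <- aliveIdx
    # greedy global assignment: nearest valid (track, candidate) pair first.
    # A candidate slightly overlapping already-claimed pixels (a contact
    # sliver with a neighbouring nucleus) is trimmed rather than discarded;
    # heavily overlapping candidates are skipped (nearer centroid has won).
    repeat {
      bestI <- NA_integer_; bestDist <- Inf; bestPix <- NULL
      for (i in pending) {
        for (cand in cands[[i]]) {
          if (cand$dist >= bestDist) break
          ov <- claimed[cand$pixels]
          if (!any(ov)) {
            bestI <- i; bestDist <- cand$dist; bestPix <- cand$pixels
            break
          } else if (mean(ov) <= 0.3 && sum(!ov) >= cfg@minAreaPx) {
            bestI <- i; bestDist <- cand$dist
            bestPix <- cand$pixels[!ov, , drop = FALSE]
            break
          }
        }
      }
      if (is.na(bestI)) break
      claimed[bestPix] <- TRUE
      m <- newNucleusMask(st[[bestI]]$id, bestPix)
      st[[bestI]]$frames <- c(st[[bestI]]$frames, f)
      st[[bestI]]$masks[[length(st[[bestI]]$masks) + 1L]] <- m
      st[[bestI]]$status <- c(st[[bestI]]$status, "tracked")
      st[[bestI]]$carry <- 0L
      pending <- setdiff(pending, bestI)
    }
    # unmatched live tracks: carry the previous mask forward (trimmed against
    # claimed pixels) or declare them lost
    for (i in pending) {
      prev <- st[[i]]$masks[[length(st[[i]]$masks)]]
      keep <- !claimed[prev@pixels]
      if (st[[i]]$carry + 1L > maxCarry || !any(keep)) {
        st[[i]]$alive <- FALSE
        st[[i]]$lostAt <- f
        next
      }
      pix <- prev@pixels[keep, , drop = FALSE]
      claimed[pix] <- TRUE
      st[[i]]$frames <- c(st[[i]]$frames, f)
      st[[i]]$masks[[length(st[[i]]$masks) + 1L]] <- newNucleusMask(st[[i]]$id, pix)
      st[[i]]$status <- c(st[[i]]$status, "carried")
      st[[i]]$carry <- st[[i]]$carry + 1L
    }
  }

  lapply(st, function(s) new("NucleusTrack",
    nucleusId = as.integer(s$id),
    frameIndex = as.integer(s$frames),
    masks = s$masks,
    status = s$status,
    lostAtFrame = s$lostAt))
}

# Local re-segmentation of one crop, anchored to the track. The threshold is
# set halfway between the crop background (median of the smoothed crop) and
# the track's own level (lower quartile of the smoothed crop at the previous
# mask position), so dim and bright nuclei are segmented alike and the mask
# boundary sits at the half-height of the blurred edge. Returns candidate
# pixel-coordinate matrices in crop coordinates.
localSegment <- function(sub, cfg, prevCrop, sigma, carveRadiusPx = 5L) {
  prevArea <- nrow(prevCrop)
  img <- if (sigma > 0) as.matrix(EBImage::gblur(sub, sigma = sigma)) else sub
  ok <- prevCrop[, 1L] >= 1L & prevCrop[, 1L] <= nrow(img) &
        prevCrop[, 2L] >= 1L & prevCrop[, 2L] <= ncol(img)
  if (!any(ok)) return(list())
  bgEst <- stats::median(img)
  # with bridging the smoothed interior is unimodal and its median is a
  # robust level; without bridging (noise-free data) the raw values are
  # bimodal across stripe and gap rows and the lower quartile tracks the
  # dimmer phase, which the threshold must stay below
  refQ <- if (sigma >= 2) 0.5 else 0.25
  ref <- as.numeric(stats::quantile(img[prevCrop[ok, , drop = FALSE]], refQ,
                                    names = FALSE))
  if (ref <= bgEst) return(list())
  # quarter-height detection threshold: low enough that the dim cap rows of
  # a striped nucleus survive detection (the drained inter-stripe level at
  # strong recruitment stays above ~0.35 of the track level), while the
  # refinement step owns the boundary and peels the blur halo afterwards
  th <- bgEst + 0.25 * (ref - bgEst)
  bw <- img > th
  if (!any(bw)) return(list())
  lab <- as.matrix(EBImage::fillHull(EBImage::bwlabel(bw)))
  counts <- tabulate(lab[lab > 0L])
  # spans are refined on a lightly smoothed crop (robust for dim nuclei);
  # halo rows are peeled on raw medians inside refineMaskRows. Size and
  # solidity gates apply to the refined mask -- the bridged blob carries a
  # blur halo that makes its own solidity meaningless.
  imgFine <- if (cfg@smoothingSigmaPx > 0)
    as.matrix(EBImage::gblur(sub, sigma = cfg@smoothingSigmaPx)) else sub
  bgFine <- stats::median(imgFine)
  bgRaw <- stats::median(sub)
  dilPrev <- NULL
  out <- list()
  for (id in which(counts >= cfg@minAreaPx & counts <= 4 * cfg@maxAreaPx)) {
    pix0 <- which(lab == id, arr.ind = TRUE)
    carved <- FALSE
    if (nrow(pix0) > 1.5 * prevArea) {
      # oversize blob: bridging can fuse near-touching nuclei into one
      # component; carve out the part near the previous mask position
      if (is.null(dilPrev)) {
        pm <- matrix(0L, nrow(img), ncol(img))
        pm[prevCrop[ok, , drop = FALSE]] <- 1L
        # the dilation covers typical one-frame motion; a tight radius is
        # deliberate -- a wide one would keep a lip of the neighbour
        dilPrev <- as.matrix(EBImage::dilate(
          pm, EBImage::makeBrush(2L * as.integer(carveRadiusPx) + 1L,
                                 shape = "disc"))) > 0
      }
      pix0 <- pix0[dilPrev[pix0], , drop = FALSE]
      if (nrow(pix0) < cfg@minAreaPx) next
      carved <- TRUE
    }
    pix <- refineMaskRows(imgFine, pix0, bgFine, peel = sigma >= 2,
                          imgRaw = sub, bgRaw = bgRaw)
    if (nrow(pix) < cfg@minAreaPx || nrow(pix) > cfg@maxAreaPx) next
    # a carved candidate may keep a thin contact lip from the neighbour, so
    # its solidity is not meaningful: the anchor to the previous mask is the
    # identity evidence there
    if (!carved && maskSolidity(pix) < cfg@minSolidity) next
    out[[length(out) + 1L]] <- pix
  }
  out
}
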