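#' Construct a SceneConfig
#'
#' See [SceneConfig-class] for the meaning of every field. Defaults emulate
#' the standard acquisition geometry (512 x 512 field, 32 stripes of width
#' 5 px, hence a 16 px gauge), a 10-fold log-uniform spread of nucleus
#' baselines, and read noise giving a signal-to-noise ratio of roughly 10 at
#' the median baseline.
#'
#' @param fieldSize,nNuclei,axesRangePx,axisRatioRange field geometry.
#' @param baselineLow,baselineFold,background intensity model.
#' @param readNoiseSd,shotNoise detector noise model.
#' @param motionSigmaPx per-frame Gaussian step of nucleus centers.
#' @param linesPerField,stripeWidthPx,stripeOffsetPx stripe geometry;
#'   `stripeOffsetPx = NA` places the first stripe center half a gauge down.
#' @param mode,ampRange,tauRiseMin,tauDecayMin,tauRecoveryMin kinetics;
#'   `ampRange = NULL` selects mode-appropriate defaults (0.8-1.4 for DDR,
#'   -0.7 to -0.5 for FRAP).
#' @param timesMin frame times in minutes; `NULL` selects a mode-appropriate
#'   default sampling out to 60 minutes (FRAP includes a pre-bleach frame at
#'   -1 min, mirroring segmentation of the unexposed first image).
#' @param seed RNG seed (bit-identical scenes for a fixed seed).
#' @return A validated [SceneConfig-class].
#' @examples
#' cfg <- sceneConfig(nNuclei = 5, seed = 1)
#' @export
sceneConfig <- function(fieldSize = c(512L, 512L), nNuclei = 20L,
                        axesRangePx = c(18, 26), axisRatioRange = c(0.7, 1),
                        baselineLow = 500, baselineFold = 10, background = 100,
                        readNoiseSd = 150, shotNoise = FALSE,
                        motionSigmaPx = 0,
                        linesPerField = 32L, stripeWidthPx = 5,
                        stripeOffsetPx = NA,
                        mode = c("DDR", "FRAP"), ampRange = NULL,
                        tauRiseMin = 5, tauDecayMin = 60, tauRecoveryMin = 30,
                        timesMin = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(ampRange))
    ampRange <- if (mode == "DDR") c(0.8, 1.4) else c(-0.7, -0.5)
  if (is.null(timesMin))
    timesMin <- if (mode == "DDR") c(0, 2, 5, 10, 15, 20, 30, 45, 60)
                else c(-1, 0, 1, 2, 5, 10, 15, 20, 30, 45, 60)
  gauge <- fieldSize[1] / linesPerField
  if (is.na(stripeOffsetPx)) stripeOffsetPx <- floor(gauge / 2)
  new("SceneConfig",
    fieldSize = as.integer(fieldSize), nNuclei = as.integer(nNuclei),
    axesRangePx = axesRangePx, axisRatioRange = axisRatioRange,
    baselineLow = baselineLow, baselineFold = baselineFold,
    background = background, readNoiseSd = readNoiseSd, shotNoise = shotNoise,
    motionSigmaPx = motionSigmaPx, linesPerField = as.integer(linesPerField),
    stripeWidthPx = stripeWidthPx, stripeOffsetPx = as.numeric(stripeOffsetPx),
    mode = mode, ampRange = ampRange, tauRiseMin = tauRiseMin,
    tauDecayMin = tauDecayMin, tauRecoveryMin = tauRecoveryMin,
    timesMin = as.numeric(timesMin), seed = as.integer(seed))
}

#' Programmed Measure-of-Striation kinetics
#'
#' The synthetic kinetic model shaping per-nucleus MS time courses:
#' * DDR (recruitment): `MS(t) = Amp * (1 - exp(-t/tauRise)) * exp(-t/tauDecay)`,
#'   rescaled so its maximum (attained at `t* = tauRise * log(1 + tauDecay/tauRise)`)
#'   equals `Amp`; `MS(t <= 0) = 0`.
#' * FRAP (bleach and recovery): `MS(t) = Amp * exp(-t/tauRecovery)` with
#'   `Amp < 0`; `MS(0) = Amp` (maximum striation immediately after the
#'   bleach) and `MS(t < 0) = 0`.
#'
#' @param tMin time(s) in minutes.
#' @param mode `"DDR"` or `"FRAP"`.
#' @param amp amplitude: peak MS (> 0) for DDR, minimum MS (in (-1, 0)) for
#'   FRAP.
#' @param tauRiseMin,tauDecayMin,tauRecoveryMin time constants in minutes.
#' @return Numeric vector of MS values, same length as `tMin`.
#' @examples
#' kineticModel(0, "DDR", amp = 1)                       # 0 by construction
#' kineticModel(30, "FRAP", amp = -0.6, tauRecoveryMin = 30)  # -0.6 * exp(-1)
#' @export
kineticModel <- function(tMin, mode = c("DDR", "FRAP"), amp,
                         tauRiseMin = 5, tauDecayMin = 60, tauRecoveryMin = 30) {
  mode <- match.arg(mode)
  if (any(c(tauRiseMin, tauDecayMin, tauRecoveryMin) <= 0))
    stop("time constants must be positive")
  if (mode == "DDR") {
    if (amp <= 0) stop("DDR amplitude must be positive")
    raw <- function(t) (1 - exp(-t / tauRiseMin)) * exp(-t / tauDecayMin)
    tStar <- tauRiseMin * log(1 + tauDecayMin / tauRiseMin)
    out <- amp * raw(pmax(tMin, 0)) / raw(tStar)
    out[tMin <= 0] <- 0
    out
  } else {
    if (amp >= 0 || amp <= -1) stop("FRAP amplitude must be in (-1, 0)")
    out <- amp * exp(-pmax(tMin, 0) / tauRecoveryMin)
    out[tMin < 0] <- 0
    out
  }
}

#' Render a synthetic striping scene with ground truth
#'
#' Places non-overlapping elliptical nuclei with log-uniform baselines on a
#' uniform background, draws the horizontal stripe band geometry, and at each
#' frame rescales stripe vs non-stripe pixels of every nucleus so that the
#' realized MS of the noiseless nucleus equals the programmed
#' [kineticModel()] value exactly:
#' * DDR: recruitment is intra-nuclear redistribution -- stripe pixels gain
#'   what inter-stripe pixels lose, preserving the total per-nucleus SID
#'   (protein relocates, it is not created);
#' * FRAP: bleaching is true signal loss in the stripes with exponential
#'   refill; inter-stripe pixels are untouched.
#'
#' Nucleus centers optionally take an isotropic Gaussian step per frame
#' (reflected at the field margin; steps that would interpenetrate another
#' nucleus are rejected). The stripe marks are material: drawn in the
#' field-fixed laser geometry at irradiation time, they then translate
#' rigidly with their nucleus. Noise (Poisson shot noise on the pre-noise
#' intensity, then Gaussian read noise) is added last. All randomness
#' derives from `cfg@seed`; the caller's RNG state is preserved.
#'
#' @param cfg a [SceneConfig-class].
#' @return List with `stack` (a [FrameStack-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' sc <- renderScene(sceneConfig(nNuclei = 3, fieldSize = c(256L, 256L),
#'                               linesPerField = 16L, readNoiseSd = 0, seed = 7))
#' sc$stack
#' @export
renderScene <- function(cfg) {
  validObject(cfg)
  withSeed(cfg@seed, renderSceneImpl(cfg))
}

renderSceneImpl <- function(cfg) {
  nr <- cfg@fieldSize[1L]; nc <- cfg@fieldSize[2L]
  nT <- length(cfg@timesMin)
  n <- cfg@nNuclei
  gauge <- nr %/% cfg@linesPerField

  # per-nucleus shape and intensity parameters
  aMaj <- stats::runif(n, cfg@axesRangePx[1L], cfg@axesRangePx[2L])
  aMin <- aMaj * stats::runif(n, cfg@axisRatioRange[1L], cfg@axisRatioRange[2L])
  phi <- stats::runif(n, 0, pi)
  baseline <- exp(stats::runif(n, log(cfg@baselineLow),
                               log(cfg@baselineLow * cfg@baselineFold)))
  amp <- stats::runif(n, min(cfg@ampRange), max(cfg@ampRange))

  centers <- placeNuclei(n, nr, nc, aMaj)

  # programmed kinetics
  msTrue <- t(vapply(seq_len(n), function(i)
    kineticModel(cfg@timesMin, cfg@mode, amp[i],
                 cfg@tauRiseMin, cfg@tauDecayMin, cfg@tauRecoveryMin),
    numeric(nT)))

  # trajectories: Gaussian random walk, reflected to keep nuclei off borders;
  # a step that would make two nuclei interpenetrate is rejected (the nucleus
  # stalls for that frame) -- cells are solid objects
  traj <- array(0, c(n, nT, 2L))
  traj[, 1L, ] <- centers
  if (nT > 1L) for (f in 2:nT) {
    step <- matrix(stats::rnorm(2L * n, 0, cfg@motionSigmaPx), n, 2L)
    pos <- matrix(traj[, f - 1L, ], n, 2L)
    margin <- aMaj + 3
    for (i in seq_len(n)) {
      cand <- pos[i, ] + step[i, ]
      cand[1L] <- reflectInto(cand[1L], margin[i], nr - margin[i])
      cand[2L] <- reflectInto(cand[2L], margin[i], nc - margin[i])
      others <- seq_len(n) != i
      if (n == 1L || all(sqrt((pos[others, 1L] - cand[1L])^2 +
                              (pos[others, 2L] - cand[2L])^2) >=
                         aMaj[i] + aMaj[others] + 2))
        pos[i, ] <- cand
    }
    traj[, f, ] <- pos
  }

  stripeCenters <- seq(cfg@stripeOffsetPx, nr, by = gauge)
  stripeCenters <- as.integer(round(stripeCenters[stripeCenters <= nr]))
  # periodic band membership in the field-fixed laser geometry
  rowInBand <- function(r) {
    u <- (r - cfg@stripeOffsetPx) %% gauge
    pmin(u, gauge - u) <= cfg@stripeWidthPx / 2 + 1e-9
  }

  frames <- vector("list", nT)
  labels <- vector("list", nT)
  for (f in seq_len(nT)) {
    img <- matrix(cfg@background, nr, nc)
    lab <- matrix(0L, nr, nc)
    for (i in seq_len(n)) {
      pix <- nucleusPixels(traj[i, f, 1L], traj[i, f, 2L],
                           aMaj[i], aMin[i], phi[i], nr, nc)
      # flat disk sitting on (and occluding) the background pedestal
      base <- rep(cfg@background + baseline[i], nrow(pix))
      # the stripes are material marks drawn at irradiation time: they
      # translate rigidly with the nucleus (quantized to whole pixels so
      # band edges stay crisp)
      dy <- round(traj[i, f, 1L] - traj[i, 1L, 1L])
      inS <- rowInBand(pix[, 1L] - dy)
      vals <- applyStriation(base, inS, msTrue[i, f], cfg@mode)
      img[pix] <- vals
      lab[pix] <- i
    }
    if (cfg@shotNoise) img[] <- stats::rpois(length(img), lambda = img)
    if (cfg@readNoiseSd > 0)
      img[] <- img + stats::rnorm(length(img), 0, cfg@readNoiseSd)
    img[img < 0] <- 0
    frames[[f]] <- img
    labels[[f]] <- lab
  }

  trajDf <- do.call(rbind, lapply(seq_len(nT), function(f)
    data.frame(frame = f, nucleus_id = seq_len(n),
               row = traj[, f, 1L], col = traj[, f, 2L])))

  kin <- data.frame(nucleus_id = seq_len(n), amp = amp,
                    baseline = baseline, a_major = aMaj, a_minor = aMin,
                    angle_rad = phi)
  kin$tau_rise <- if (cfg@mode == "DDR") cfg@tauRiseMin else NA_real_
  kin$tau_decay <- if (cfg@mode == "DDR") cfg@tauDecayMin else NA_real_
  kin$tau_recovery <- if (cfg@mode == "FRAP") cfg@tauRecoveryMin else NA_real_

  list(
    stack = frameStack(frames, cfg@timesMin,
                       channelLabel = sprintf("synthetic-%s", cfg@mode)),
    truth = new("GroundTruth",
      labels = labels, trajectories = trajDf, msTrue = msTrue,
      stripeCenterRows = stripeCenters, gaugePx = as.integer(gauge),
      widthPx = cfg@stripeWidthPx, kinetics = kin, mode = cfg@mode))
}

# Rejection-sample nucleus centers with pairwise spacing that keeps ellipses
# disjoint; bounded retries (1000 per nucleus).
placeNuclei <- function(n, nr, nc, aMaj, maxTries = 1000L) {
  centers <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    margin <- aMaj[i] + 3
    if (2 * margin >= min(nr, nc)) stop("nucleus too large for the field")
    placed <- FALSE
    for (k in seq_len(maxTries)) {
      p <- c(stats::runif(1, margin, nr - margin),
             stats::runif(1, margin, nc - margin))
      if (i == 1L) { centers[i, ] <- p; placed <- TRUE; break }
      dd <- sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                          matrix(p, i - 1L, 2L, byrow = TRUE))^2))
      if (all(dd >= aMaj[i] + aMaj[seq_len(i - 1L)] + 4)) {
        centers[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping nuclei; reduce nNuclei or axes")
  }
  centers
}

reflectInto <- function(x, lo, hi) {
  out <- x
  below <- out < lo; out[below] <- 2 * lo[below] - out[below]
  above <- out > hi; out[above] <- 2 * hi[above] - out[above]
  pmin(pmax(out, lo), hi)
}

# Pixel set of one (possibly rotated) ellipse, as an integer (row, col)
# coordinate matrix. Nuclei are rendered as flat disks with a sharp edge so
# that the rendered mask, the segmented mask and the stripe-band set can
# coincide exactly on noiseless scenes.
nucleusPixels <- function(cr, cc, aMaj, aMin, phi, nr, nc) {
  r1 <- max(1L, floor(cr - aMaj)); r2 <- min(nr, ceiling(cr + aMaj))
  c1 <- max(1L, floor(cc - aMaj)); c2 <- min(nc, ceiling(cc + aMaj))
  rows <- r1:r2; cols <- c1:c2
  dy <- rep(rows - cr, times = length(cols))
  dx <- rep(cols - cc, each = length(rows))
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  keep <- (u / aMaj)^2 + (v / aMin)^2 <= 1
  cbind(as.integer(round(dy[keep] + cr)), as.integer(round(dx[keep] + cc)))
}

# Rescale stripe vs non-stripe pixels of one nucleus so the realized MS on
# the true mask equals `m` exactly, given base intensities `base` and stripe
# membership `inStripe`. DDR preserves the total SID (redistribution); FRAP
# removes signal from the stripes only.
applyStriation <- function(base, inStripe, m, mode) {
  if (m == 0) return(base)   # flat base: s = q = 1
  aM <- length(base); aS <- sum(inStripe)
  if (aS == 0L || aS == aM) return(base)
  j0 <- sum(base); jS0 <- sum(base[inStripe])
  fA <- aS / aM           # stripe area fraction
  g <- jS0 / j0           # stripe SID fraction of the base profile
  if (mode == "DDR") {
    s <- (1 + m) * fA / g
    q <- (1 - s * g) / (1 - g)
    if (q < 0)
      stop("programmed MS too large for the stripe fraction (inter-stripe signal would go negative)")
  } else {
    denom <- 1 - (1 + m) * fA
    if (denom <= 0) stop("FRAP amplitude incompatible with stripe fraction")
    s <- (1 + m) * fA * (1 - g) / (g * denom)
    q <- 1
  }
  out <- base
  out[inStripe] <- base[inStripe] * s
  out[!inStripe] <- base[!inStripe] * q
  out
}
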