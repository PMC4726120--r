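test_that("stripe orientation is recovered from planted patterns", {
  mask <- circleMask(81)
  vert <- stripedImage(mask, dPx = 12, pPx = 4, widthPx = 3)
  expect_equal(rotateToVertical(vert, mask)$angleDeg, 0)
  # horizontal stripes (the raw scan orientation) resolve to 90 degrees
  horiz <- t(vert)
  expect_equal(rotateToVertical(horiz, t(mask))$angleDeg, 90)
  # a 30-degree planted rotation is recovered within one grid step
  rot <- as.matrix(EBImage::rotate(horiz, 30, filter = "bilinear", bg.col = 0))
  rmask <- as.matrix(EBImage::rotate(t(mask) * 1, 30, filter = "none", bg.col = 0)) >= 0.5
  ang <- rotateToVertical(rot, rmask)$angleDeg
  # EBImage::rotate(. , a) on [row, col] data shifts the Radon angle by -a
  expect_lte(min(abs(ang - 60), 180 - abs(ang - 60)), 1)
  expect_error(rotateToVertical(matrix(0, 4, 4), matrix(FALSE, 4, 4)), "empty mask")
})

test_that("the rotated output has vertical stripes whatever the planted angle", {
  mask <- circleMask(81)
  img <- stripedImage(mask, dPx = 12, pPx = 4, widthPx = 3)
  for (a in c(15, 45, 77, 122)) {
    rot <- as.matrix(EBImage::rotate(img, a, filter = "bilinear", bg.col = 0))
    rmask <- as.matrix(EBImage::rotate(mask * 1, a, filter = "none", bg.col = 0)) >= 0.5
    rv <- rotateToVertical(rot, rmask)
    fit <- fitStripes(rv$image, rv$mask, widthPx = 3, dRange = c(6, 18), pWindowPx = 6)
    expect_true(fit@ok)
    expect_equal(fit@dPx, 12L)
  }
})

test_that("the objective matches its closed form and the pixel-sum oracle", {
  mask <- matrix(TRUE, 30, 40)
  # bands of intensity 2 on background 1, gauge 10, 3 columns per band
  img <- stripedImage(mask, dPx = 10, pPx = 2, widthPx = 3, bright = 2, bg = 1)
  w <- sum(img[1, ] == 2) / 4                     # bright columns per period
  expect_equal(w, 3)
  fTrue <- stripeObjective(img, mask, dPx = 10, pPx = 2, widthPx = 3)
  expect_equal(fTrue, 2 * 10 / (10 + 3))          # mean-ratio closed form
  expect_equal(fTrue, mean(img[stripedImage(mask, 10, 2, 3, TRUE, FALSE) == 1]) /
                 mean(img))                       # brute-force pixel sums
  # anti-phase sampling hits the background
  expect_lt(stripeObjective(img, mask, dPx = 10, pPx = 7, widthPx = 3), 1)
  # a constant image gives F = 1 for every geometry
  for (D in c(8, 10, 13)) for (P in c(0, 3, 6))
    expect_equal(stripeObjective(matrix(5, 30, 40), mask, D, P, 3), 1)
  expect_error(stripeObjective(img, mask, dPx = 3, pPx = 0, widthPx = 3), "exceed")
})

test_that("fitStripes equals the independently coded exhaustive search", {
  set.seed(401)
  for (i in 1:50) {
    size <- 64L
    mask <- circleMask(size, radius = sample(18:28, 1))
    dTrue <- sample(8:14, 1)
    pTrue <- sample(0:(dTrue - 1), 1)
    img <- stripedImage(mask, dTrue, pTrue, widthPx = 3,
                        bright = runif(1, 2, 4), bg = 1)
    img[mask] <- img[mask] + rnorm(sum(mask), 0, 0.15)
    img[img < 0] <- 0
    fit <- fitStripes(img, mask, widthPx = 3, dRange = c(6, 16), pWindowPx = 8)
    orc <- oracleFitStripes(img, mask, widthPx = 3, dRange = c(6, 16), pWindowPx = 8)
    expect_identical(as.integer(fit@dPx), as.integer(orc$dPx))
    expect_identical(as.integer(fit@pPx), as.integer(orc$pPx))
    expect_equal(fit@fValue, orc$fValue, tolerance = 1e-12)
  }
})

test_that("dark-stripe fitting recovers a bleached pattern", {
  set.seed(402)
  mask <- circleMask(64, 24)
  img <- stripedImage(mask, dPx = 12, pPx = 5, widthPx = 3, bright = 0.3, bg = 1)
  fit <- fitStripes(img, mask, widthPx = 3, dRange = c(6, 18), pWindowPx = 8,
                    direction = "dark")
  expect_true(fit@ok)
  expect_equal(fit@dPx, 12L)
  expect_lt(fit@fValue, 1)
  rec <- computeMS(img, mask, fit)
  expect_lt(rec$ms, 0)
  orc <- oracleFitStripes(img, mask, 3, c(6, 18), 8, direction = "dark")
  expect_identical(as.integer(fit@dPx), as.integer(orc$dPx))
  expect_identical(as.integer(fit@pPx), as.integer(orc$pPx))
})

test_that("noisy gauge recovery succeeds in at least 95 percent of replicates", {
  set.seed(403)
  hits <- 0L
  for (i in 1:100) {
    mask <- circleMask(64, 25)
    img <- stripedImage(mask, dPx = 12, pPx = sample(0:11, 1), widthPx = 3,
                        bright = 3, bg = 1)
    # Poisson-like noise at SNR >= 5 on the band intensity
    img[mask] <- pmax(0, img[mask] + rnorm(sum(mask), 0, 0.5))
    fit <- fitStripes(img, mask, widthPx = 3, dRange = c(6, 18), pWindowPx = 8)
    hits <- hits + (fit@ok && fit@dPx == 12L)
  }
  expect_gte(hits, 95L)
})

test_that("the MS obeys its defining arithmetic", {
  # mask of 100 px, total SID 1000; a 20 px stripe region holding SID 400
  mask <- matrix(TRUE, 10, 10)
  img <- matrix(600 / 80, 10, 10)
  img[, 9:10] <- 400 / 20
  fit <- new("StripeFit", angleDeg = 0, dPx = 12L, pPx = 0L, widthPx = 2.5,
             fValue = 1, ok = TRUE)  # band = columns 9:10 (|c-10|<=1.25)
  rec <- computeMS(img, mask, fit)
  expect_equal(rec$j_expt, 200)
  expect_equal(rec$j_meas, 400)
  expect_equal(rec$ms, 1.0)
  # all signal concentrated in a stripe fraction f gives MS = 1/f - 1
  img2 <- matrix(0, 10, 10); img2[, 9:10] <- 5   # f = 0.2
  rec2 <- computeMS(img2, mask, fit)
  expect_equal(rec2$ms, 1 / 0.2 - 1)
  # a homogeneous nucleus has MS = 0 for any geometry
  rec3 <- computeMS(matrix(7, 10, 10), mask, fit)
  expect_equal(rec3$ms, 0)
  # an all-zero nucleus is flagged, not scored
  rec4 <- computeMS(matrix(0, 10, 10), mask, fit)
  expect_true(rec4$flagged)
  expect_true(is.na(rec4$ms))
})

test_that("MS is scale invariant and bounded below by -1", {
  set.seed(404)
  for (i in 1:20) {
    mask <- circleMask(48, sample(14:20, 1))
    img <- stripedImage(mask, 12, sample(0:11, 1), 3, bright = runif(1, 0.1, 5))
    img[mask] <- pmax(0, img[mask] + rnorm(sum(mask), 0, 0.1))
    fit <- fitStripes(img, mask, 3, c(6, 18), 8)
    ref <- computeMS(img, mask, fit)$ms
    expect_gte(ref, -1)
    for (cc in c(0.1, 7.3, 1000))
      expect_lt(abs(computeMS(cc * img, mask, fit)$ms - ref), 1e-9)
  }
})
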