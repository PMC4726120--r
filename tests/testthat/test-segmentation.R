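# Frame 1 of a rendered scene is the pre-irradiation image: homogeneous
# nuclei over a 10-fold baseline range, the regime the cascade exists for.

test_that("degenerate frames are handled", {
  expect_equal(segmentCascade(matrix(0, 32, 32)), list())
  expect_error(segmentCascade(matrix(-1, 8, 8)), "non-negative")
  expect_error(segmentCascade(matrix(NA_real_, 8, 8)), "finite")
})

test_that("the cascade finds every nucleus across a 10-fold intensity range", {
  sc <- renderScene(sceneConfig(nNuclei = 10L, readNoiseSd = 40, seed = 201))
  frame <- getFrame(sc$stack, 1L)
  masks <- segmentCascade(frame, segmentationConfig())
  expect_length(masks, 10L)
  lab <- gtLabels(sc$truth)[[1L]]
  hit <- integer(0)
  for (m in masks) {
    gt <- lab[maskPixels(m)]
    gid <- as.integer(names(which.max(table(gt))))
    overlap <- sum(gt == gid) / max(maskArea(m), sum(lab == gid))
    expect_gt(overlap, 0.95)
    hit <- c(hit, gid)
  }
  expect_setequal(hit, 1:10)
  # determinism: identical call, identical masks
  again <- segmentCascade(frame, segmentationConfig())
  expect_identical(lapply(again, maskPixels), lapply(masks, maskPixels))
})

test_that("planted distractors are rejected by the size and solidity gates", {
  sc <- renderScene(sceneConfig(nNuclei = 10L, readNoiseSd = 40, seed = 202))
  frame <- getFrame(sc$stack, 1L)
  # a tiny bright blob far below minAreaPx
  frame[10:14, 10:14] <- 4000
  # a U-shaped object (three sides of a thick rectangle ring, low solidity),
  # painted in a spot free of planted nuclei
  lab1 <- gtLabels(sc$truth)[[1L]]
  spot <- NULL
  for (r0 in seq(20, 430, by = 30)) for (c0 in seq(20, 420, by = 30)) {
    if (is.null(spot) && all(lab1[r0:(r0 + 70), c0:(c0 + 80)] == 0L))
      spot <- c(r0, c0)
  }
  u <- matrix(FALSE, 512, 512)
  u[spot[1] + 0:60, spot[2] + 0:12] <- TRUE
  u[spot[1] + 0:60, spot[2] + 60:72] <- TRUE
  u[spot[1] + 48:60, spot[2] + 0:72] <- TRUE
  frame[u] <- 4000
  expect_gt(sum(u), 500)                      # big enough to pass the area gate
  masks <- segmentCascade(frame, segmentationConfig())
  expect_length(masks, 10L)
  for (m in masks) expect_lt(sum(u[maskPixels(m)]) / maskArea(m), 0.05)
})

test_that("raising the gates never increases the number of accepted masks", {
  sc <- renderScene(sceneConfig(nNuclei = 8L, readNoiseSd = 40, seed = 203))
  frame <- getFrame(sc$stack, 1L)
  base <- length(segmentCascade(frame, segmentationConfig()))
  expect_lte(length(segmentCascade(frame, segmentationConfig(minSolidity = 0.97))), base)
  expect_lte(length(segmentCascade(frame, segmentationConfig(minAreaPx = 1200))), base)
})

test_that("the cascade recovers more nuclei than a single global Otsu threshold", {
  sc <- renderScene(sceneConfig(nNuclei = 12L, readNoiseSd = 40, seed = 204))
  frame <- getFrame(sc$stack, 1L)
  lab <- gtLabels(sc$truth)[[1L]]
  recovered <- function(masks) {
    length(unique(vapply(masks, function(m) {
      gt <- lab[maskPixels(m)]
      gid <- as.integer(names(which.max(table(gt))))
      if (sum(gt == gid) / sum(lab == gid) >= 0.5) gid else NA_integer_
    }, integer(1))))
  }
  cascade <- segmentCascade(frame, segmentationConfig())
  # Otsu baseline: one global threshold, then the same gates
  th <- EBImage::otsu(EBImage::Image(frame / max(frame))) * max(frame)
  bw <- as.matrix(EBImage::fillHull(EBImage::bwlabel(frame > th)))
  counts <- tabulate(bw[bw > 0])
  otsuMasks <- list()
  for (id in which(counts >= 500 & counts <= 15000)) {
    pix <- which(bw == id, arr.ind = TRUE)
    otsuMasks[[length(otsuMasks) + 1L]] <- pix
  }
  otsuHits <- length(unique(vapply(otsuMasks, function(pix) {
    gt <- lab[pix]
    gid <- as.integer(names(which.max(table(gt))))
    if (sum(gt == gid) / sum(lab == gid) >= 0.5) gid else NA_integer_
  }, integer(1))))
  expect_gt(recovered(cascade), otsuHits)
})

test_that("Hoechst-channel segmentation positions masks by the DNA channel only", {
  sc <- renderScene(sceneConfig(nNuclei = 5L, readNoiseSd = 40, seed = 205))
  dna <- getFrame(sc$stack, 1L)            # homogeneous nuclei: a DNA stain proxy
  masks <- segmentHoechst(dna, segmentationConfig())
  expect_length(masks, 5L)
  # identical contract to the cascade on the same frame
  same <- segmentCascade(dna, segmentationConfig())
  expect_identical(lapply(masks, maskPixels), lapply(same, maskPixels))
  expect_equal(segmentHoechst(matrix(0, 64, 64)), list())
})
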