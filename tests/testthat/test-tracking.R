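test_that("static nuclei are tracked through every frame with sub-pixel drift", {
  sc <- renderScene(sceneConfig(fieldSize = c(384L, 384L), nNuclei = 6L,
                                linesPerField = 24L, readNoiseSd = 0,
                                motionSigmaPx = 0,
                                timesMin = seq(0, 38, by = 2), seed = 301))
  masks <- segmentCascade(getFrame(sc$stack, 1L), segmentationConfig(smoothingSigmaPx = 0))
  tracks <- trackNuclei(sc$stack, masks, cfg = segmentationConfig(smoothingSigmaPx = 0),
                        bridgeSigmaPx = 0)
  expect_length(tracks, 6L)
  for (tr in tracks) {
    expect_false(isLost(tr))
    expect_equal(tr@frameIndex, 1:20)
    cen <- vapply(tr@masks, maskCentroid, numeric(2))
    drift <- sqrt(colSums((cen - cen[, 1L])^2))
    expect_lt(max(drift), 1)
  }
})

test_that("Brownian motion preserves identity and no pixel is claimed twice", {
  sc <- renderScene(sceneConfig(nNuclei = 10L, motionSigmaPx = 3,
                                readNoiseSd = 150, baselineLow = 1400,
                                baselineFold = 1,
                                timesMin = seq(0, 25, by = 5), seed = 302))
  masks <- segmentCascade(getFrame(sc$stack, 1L), segmentationConfig())
  tracks <- trackNuclei(sc$stack, masks, searchRadiusPx = 20)
  expect_length(tracks, 10L)
  asg <- trackAssignments(sc, tracks)
  for (f in seq_len(ncol(asg))) {
    got <- asg[!is.na(asg[, f]), f]
    expect_equal(sort(got), 1:10)           # bijection to ground-truth ids
  }
  # each track follows ONE ground-truth nucleus throughout
  for (i in seq_len(nrow(asg))) expect_length(unique(stats::na.omit(asg[i, ])), 1L)
  # disjointness: no pixel claimed by two tracks in any frame
  for (f in seq_len(ncol(asg))) {
    claimed <- matrix(FALSE, 512, 512)
    for (tr in tracks) {
      k <- match(f, tr@frameIndex)
      if (is.na(k)) next
      pix <- maskPixels(tr@masks[[k]])
      expect_false(any(claimed[pix]))
      claimed[pix] <- TRUE
    }
  }
  # determinism
  again <- trackNuclei(sc$stack, masks, searchRadiusPx = 20)
  expect_identical(lapply(again, function(t) t@frameIndex),
                   lapply(tracks, function(t) t@frameIndex))
})

test_that("a teleported nucleus loses its track; the others are unaffected", {
  sc <- renderScene(sceneConfig(fieldSize = c(384L, 384L), nNuclei = 4L,
                                linesPerField = 24L, readNoiseSd = 0,
                                motionSigmaPx = 0,
                                timesMin = seq(0, 16, by = 2), seed = 303))
  frames <- lapply(seq_len(nFrames(sc$stack)), function(f) getFrame(sc$stack, f))
  # teleport nucleus 1 by 150 px (wrap) from frame 5 on
  lab <- gtLabels(sc$truth)
  for (f in 5:length(frames)) {
    pix <- which(lab[[f]] == 1L, arr.ind = TRUE)
    vals <- frames[[f]][pix]
    frames[[f]][pix] <- 0
    shifted <- cbind((pix[, 1L] + 150L - 1L) %% 384L + 1L, pix[, 2L])
    frames[[f]][shifted] <- vals
  }
  stack2 <- frameStack(frames, timesMin(sc$stack))
  masks <- segmentCascade(frames[[1L]], segmentationConfig(smoothingSigmaPx = 0))
  tracks <- trackNuclei(stack2, masks, searchRadiusPx = 20,
                        cfg = segmentationConfig(smoothingSigmaPx = 0),
                        bridgeSigmaPx = 0, maxCarry = 2L)
  lab1 <- lab[[1L]]
  gids <- vapply(tracks, function(tr)
    as.integer(names(which.max(table(lab1[maskPixels(tr@masks[[1L]])])))), integer(1))
  teleported <- tracks[[which(gids == 1L)]]
  expect_true(isLost(teleported))
  expect_true(teleported@lostAtFrame >= 5L &&
              teleported@lostAtFrame <= 5L + 2L + 1L)
  for (tr in tracks[gids != 1L]) expect_false(isLost(tr))
})

test_that("tracking rejects invalid inputs", {
  fs <- frameStack(matrix(1, 8, 8), 0)
  expect_error(trackNuclei(fs, list()), "no initial masks")
  sc <- renderScene(sceneConfig(fieldSize = c(256L, 256L), nNuclei = 2L,
                                linesPerField = 16L, seed = 304))
  masks <- segmentCascade(getFrame(sc$stack, 1L), segmentationConfig())
  expect_error(trackNuclei(sc$stack, masks, searchRadiusPx = 0), "searchRadiusPx")
})
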