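test_that("the kinetic model honours its construction contracts", {
  # recruitment starts from zero
  expect_equal(kineticModel(0, "DDR", amp = 1), 0)
  expect_equal(kineticModel(-3, "DDR", amp = 1), 0)
  # rescaling makes the maximum equal the amplitude exactly
  tGrid <- seq(0, 300, by = 0.01)
  expect_equal(max(kineticModel(tGrid, "DDR", amp = 1, tauRiseMin = 5,
                                tauDecayMin = 60)), 1, tolerance = 1e-6)
  expect_equal(max(kineticModel(tGrid, "DDR", amp = 0.7, tauRiseMin = 2,
                                tauDecayMin = 40)), 0.7, tolerance = 1e-6)
  # FRAP: exponential recovery from the bleach depth
  expect_equal(kineticModel(30, "FRAP", amp = -0.6, tauRecoveryMin = 30),
               -0.6 * exp(-1))
  expect_equal(kineticModel(0, "FRAP", amp = -0.6), -0.6)
  expect_error(kineticModel(1, "DDR", amp = -1), "positive")
  expect_error(kineticModel(1, "FRAP", amp = 0.5), "in \\(-1, 0\\)")
  expect_error(kineticModel(1, "DDR", amp = 1, tauRiseMin = 0), "positive")
})

test_that("scenes are bit-identical for a fixed seed", {
  cfg <- sceneConfig(fieldSize = c(256L, 256L), nNuclei = 3L,
                     linesPerField = 16L, motionSigmaPx = 2, seed = 701)
  a <- renderScene(cfg)
  b <- renderScene(cfg)
  expect_identical(a$stack@frames, b$stack@frames)
  expect_identical(gtLabels(a$truth), gtLabels(b$truth))
  # the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(renderScene(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("labels, counts and kinetics match the configuration", {
  cfg <- sceneConfig(nNuclei = 15L, seed = 702)
  sc <- renderScene(cfg)
  for (lab in gtLabels(sc$truth))
    expect_equal(sort(unique(as.vector(lab[lab > 0]))), 1:15)
  expect_equal(dim(msTrue(sc$truth)), c(15L, length(cfg@timesMin)))
  # DDR curves start at zero striation
  expect_true(all(msTrue(sc$truth)[, 1L] == 0))
  # placement fails loudly when the field cannot hold the nuclei
  expect_error(renderScene(sceneConfig(fieldSize = c(128L, 128L), nNuclei = 40L,
                                       linesPerField = 8L, seed = 1)),
               "non-overlapping")
})

test_that("the rendered striation realizes the programmed MS exactly", {
  cfg <- sceneConfig(fieldSize = c(256L, 256L), nNuclei = 1L, linesPerField = 16L,
                     readNoiseSd = 0, motionSigmaPx = 0, seed = 703)
  sc <- renderScene(cfg)
  for (f in seq_len(nFrames(sc$stack))) {
    lab <- gtLabels(sc$truth)[[f]]
    pix <- which(lab == 1L, arr.ind = TRUE)
    inS <- pix[, 1L] %in% unlist(lapply(sc$truth@stripeCenterRows,
                                        function(s) (s - 2):(s + 2)))
    frame <- getFrame(sc$stack, f)
    jM <- sum(frame[pix[inS, , drop = FALSE]])
    jE <- sum(frame[pix]) * sum(inS) / nrow(pix)
    expect_lt(abs((jM - jE) / jE - msTrue(sc$truth)[1L, f]), 1e-6)
  }
})

test_that("DDR recruitment redistributes signal at constant total SID", {
  cfg <- sceneConfig(fieldSize = c(256L, 256L), nNuclei = 3L, linesPerField = 16L,
                     readNoiseSd = 0, motionSigmaPx = 0, seed = 704)
  sc <- renderScene(cfg)
  for (i in 1:3) {
    sid <- vapply(seq_len(nFrames(sc$stack)), function(f)
      sum(getFrame(sc$stack, f)[gtLabels(sc$truth)[[f]] == i]), numeric(1))
    expect_equal(sid, rep(sid[1L], length(sid)), tolerance = 1e-12)
  }
})

test_that("solid nuclei never interpenetrate while moving", {
  cfg <- sceneConfig(nNuclei = 12L, motionSigmaPx = 4, seed = 705,
                     timesMin = seq(0, 95, by = 5))
  sc <- renderScene(cfg)
  tj <- sc$truth@trajectories
  ax <- sc$truth@kinetics$a_major
  for (f in unique(tj$frame)) {
    p <- tj[tj$frame == f, ]
    d <- as.matrix(dist(p[, c("row", "col")]))
    lim <- outer(ax, ax, "+")
    diag(d) <- Inf
    expect_true(all(d >= lim))
  }
})
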