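test_that("the Kruskal-Wallis statistic matches the hand-derived value", {
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)   # 12/(6*7)*(6^2/3 + 15^2/3) - 3*7
  # identical groups are perfectly symmetric
  kw0 <- kruskalWallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)
  # fully degenerate data (all values equal)
  kwd <- kruskalWallis(list(c(2, 2), c(2, 2)))
  expect_equal(kwd$H, 0); expect_equal(kwd$p, 1)
  expect_error(kruskalWallis(list(1:3)), "two or more")
  expect_error(kruskalWallis(list(1:3, numeric(0))), "at least one finite")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(601)
  for (i in 1:10) {
    g <- list(rnorm(8), rnorm(8, 1), rnorm(8, -1))
    h0 <- kruskalWallis(g)$H
    expect_equal(kruskalWallis(lapply(g, exp))$H, h0)
    expect_equal(kruskalWallis(lapply(g, function(x) 3 * x - 7))$H, h0)
    expect_equal(kruskalWallis(lapply(g, function(x) atan(x)^3 + x))$H, h0)
  }
})

test_that("type-I error of the test is near the nominal level", {
  set.seed(602)
  rej <- vapply(1:1000, function(i)
    kruskalWallis(list(rnorm(25), rnorm(25), rnorm(25)))$p < 0.05, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("compareToMock detects a planted shift and respects the null", {
  set.seed(603)
  mock <- data.frame(amp = rlnorm(100, 0, 0.3))
  up <- data.frame(amp = rlnorm(100, 0, 0.3) * 1.5)
  cmp <- suppressWarnings(compareToMock(up, mock, parameters = "amp"))
  expect_true(cmp$significant)
  expect_equal(cmp$direction, "up")
  null <- data.frame(amp = rlnorm(100, 0, 0.3))
  cmpn <- suppressWarnings(compareToMock(null, mock, parameters = "amp", minCells = 50))
  # direction is ns exactly when not significant
  expect_equal(cmpn$direction == "ns", !cmpn$significant)
  expect_error(compareToMock(up, NULL), "missing mock")
})

test_that("discordant biological replicates are reported as no effect", {
  set.seed(604)
  mock <- data.frame(amp = rlnorm(200, 0, 0.3), replicate = rep(1:2, each = 100))
  treated <- data.frame(
    amp = c(rlnorm(100, 0, 0.3) * 2,      # replicate 1: strong effect
            rlnorm(100, 0, 0.3)),          # replicate 2: null
    replicate = rep(1:2, each = 100))
  cmp <- suppressWarnings(compareToMock(treated, mock, parameters = "amp"))
  expect_false(cmp$significant)
  expect_equal(cmp$direction, "ns")
  # concordant replicates stay significant
  treated2 <- data.frame(amp = rlnorm(200, 0, 0.3) * 2,
                         replicate = rep(1:2, each = 100))
  cmp2 <- suppressWarnings(compareToMock(treated2, mock, parameters = "amp"))
  expect_true(cmp2$significant)
  expect_equal(cmp2$direction, "up")
})

test_that("the full comparison holds its type-I error and power", {
  set.seed(605)
  # null: treated and mock from the same distribution, 300 repetitions
  rejNull <- vapply(1:300, function(i) {
    suppressWarnings(compareToMock(data.frame(amp = rnorm(100)),
                                   data.frame(amp = rnorm(100)),
                                   parameters = "amp"))$significant
  }, logical(1))
  expect_lte(mean(rejNull), 0.05 + 0.02 + 0.025)  # binomial noise margin at n=300
  # power: a 2x shift at n = 100/group is essentially always detected
  rejShift <- vapply(1:100, function(i) {
    suppressWarnings(compareToMock(data.frame(amp = rlnorm(100, 0, 0.4) * 2),
                                   data.frame(amp = rlnorm(100, 0, 0.4)),
                                   parameters = "amp"))$significant
  }, logical(1))
  expect_gte(mean(rejShift), 0.95)
})

test_that("screenSummary builds the compounds-by-parameters code table", {
  set.seed(606)
  mock <- data.frame(amp = rnorm(60, 1), relax = rnorm(60, -0.01, 0.002))
  hit <- data.frame(amp = rnorm(60, 2), relax = rnorm(60, -0.01, 0.002))
  cmps <- list(
    compoundA = suppressWarnings(compareToMock(hit, mock,
                  parameters = c("amp", "relax"), minCells = 50)),
    compoundB = suppressWarnings(compareToMock(mock, mock,
                  parameters = c("amp", "relax"), minCells = 50)))
  tab <- screenSummary(cmps)
  expect_equal(tab$compound, c("compoundA", "compoundB"))
  expect_equal(tab$amp, c("up", "ns"))
  expect_equal(tab$relax[2], "ns")
})
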