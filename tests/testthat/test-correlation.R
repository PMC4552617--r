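# Short-axis correlation statistic and its readouts.

test_that("autocorrelation matches the brute-force oracle on random images", {
  set.seed(19)
  for (rep in 1:3) {
    img <- matrix(runif(32 * 32, 0, 5), 32, 32)
    cf <- suppressWarnings(rowAutocorrelation(img, maxLag = 0.8,
                                              binHeight = 1.6,
                                              pixelSize = 0.1))
    oracle <- bruteCorrelation(img, img, 0.8, 1.6, 0.1)
    expect_equal(values(cf), oracle, tolerance = 1e-10)
  }
})

test_that("two parallel vertical lines give secondary maxima at the separation", {
  img <- matrix(0, 32, 32)
  img[, 10] <- 1; img[, 16] <- 1    # separation 6 px = 0.6 um
  cf <- suppressWarnings(rowAutocorrelation(img, pixelSize = 0.1))
  pk <- secondaryPeaks(cf)
  expect_equal(pk[1], 0.6, tolerance = 1e-6)
  # values are symmetric in the lag to machine precision
  v <- values(cf)
  expect_equal(v, rev(v), tolerance = 1e-12)
})

test_that("a single line gives one maximum at zero lag with monotone decay", {
  img <- matrix(0, 32, 32); img[, 16] <- 1
  cf <- suppressWarnings(rowAutocorrelation(img, pixelSize = 0.1))
  v <- values(cf); lag <- lags(cf)
  expect_equal(lag[which.max(v)], 0)
  right <- v[lag >= 0 & lag <= 0.5]
  expect_true(all(diff(right) <= 1e-12))
  expect_identical(secondaryPeaks(cf), numeric(0))
})

test_that("cross-correlation of an image with itself is the autocorrelation", {
  set.seed(20)
  img <- matrix(runif(32 * 32), 32, 32)
  auto <- suppressWarnings(rowAutocorrelation(img, pixelSize = 0.1))
  cross <- suppressWarnings(crossCorrelation(img, img, pixelSize = 0.1))
  expect_equal(values(auto), values(cross))
  expect_error(crossCorrelation(img, img[1:16, 1:16]))
})

test_that("cross-correlation peaks at the applied shift", {
  img <- matrix(0, 32, 32); img[, 12] <- 1
  shifted <- matrix(0, 32, 32); shifted[, 17] <- 1   # +5 px = 0.5 um
  cf <- suppressWarnings(crossCorrelation(img, shifted, pixelSize = 0.1))
  expect_equal(lags(cf)[which.max(values(cf))], 0.5)
  oracle <- bruteCorrelation(img, shifted, 1, 3.2, 0.1)
  expect_equal(values(cf), oracle, tolerance = 1e-10)
})

test_that("correlation is bilinear: doubling an image scales it fourfold", {
  set.seed(21)
  img <- matrix(runif(32 * 32, 0, 3), 32, 32)
  v1 <- values(suppressWarnings(rowAutocorrelation(img, pixelSize = 0.1)))
  v2 <- values(suppressWarnings(rowAutocorrelation(2 * img,
                                                   pixelSize = 0.1)))
  expect_equal(v2, 4 * v1, tolerance = 1e-10)
})

test_that("secondary peaks on a cosine sit at the period; flat is empty", {
  lag <- seq(-1, 1, by = 0.05)
  p <- 0.62
  cf <- CorrelationFunction(lag, cos(2 * pi * lag / p))
  pk <- secondaryPeaks(cf)
  expect_equal(pk[1], p, tolerance = 0.01)
  expect_identical(secondaryPeaks(CorrelationFunction(lag, rep(1, 41))),
                   numeric(0))
})

test_that("membrane score behaves at its extremes", {
  lag <- seq(-1, 1, by = 0.1)
  v <- ifelse(lag == 0, 1, 0)
  expect_equal(membraneScore(CorrelationFunction(lag, v), 0.6), 0)
  expect_equal(membraneScore(CorrelationFunction(lag, rep(2, 21)), 0.6), 1)
})

test_that("time course normalization scales the maximal zero-lag value to one", {
  lag <- seq(-0.5, 0.5, by = 0.1)
  mk <- function(a) CorrelationFunction(lag, a * exp(-abs(lag) * 4))
  # one nonzero time point: its zero-lag becomes 1
  tc <- normalizeTimecourse(list(mk(0), mk(5), mk(0)),
                            intensities = c(0, 2, 0), times = c(0, 5, 10))
  expect_equal(max(values(tc)), 1)
  expect_equal(values(tc)[2, 6], 1)
  expect_true(all(values(tc)[c(1, 3), ] == 0))
  expect_equal(tc@normalization, "zero-lag-max-one")
  expect_error(normalizeTimecourse(list(mk(0), mk(0)), c(0, 0)))
  # zero-lag tracks relative intensity for a constant shape
  tc2 <- normalizeTimecourse(list(mk(1), mk(4)), intensities = c(1, 2))
  expect_equal(values(tc2)[1, 6] / values(tc2)[2, 6], 0.5)
})

test_that("membrane and cytosolic cells separate by per-cell membrane score", {
  set.seed(22)
  acq <- Acquisition(dim = c(56L, 24L), nFrames = 2L)
  nPer <- 25L
  scoreOne <- function(mode) {
    cell <- CellGeometry(center = c(1.2, 2.8), orientation = 0,
                         length = 4, width = 0.6)
    em <- seedEmitters(cell, mode, 40)
    sim <- simulateTimesampling(cell, em, noBleach(), acq)
    cf <- suppressWarnings(rowAutocorrelation(
      discoidalFilter(sim$stack)))
    membraneScore(cf, 0.6)
  }
  mem <- vapply(seq_len(nPer), function(i) scoreOne("membrane"),
                numeric(1))
  cyt <- vapply(seq_len(nPer), function(i) scoreOne("cytosolic"),
                numeric(1))
  expect_gt(mean(mem), mean(cyt))
  expect_gt(min(mem), max(cyt))
})
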