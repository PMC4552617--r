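# Focus detection, Gaussian fitting, super-resolution rendering, maps.

test_that("detection returns nothing on blank images or infinite thresholds", {
  blank <- matrix(0, 32, 32)
  expect_identical(nrow(detectFoci(blank)), 0L)
  img <- matrix(rnorm(32 * 32, 10, 1), 32, 32)
  expect_identical(nrow(detectFoci(img, Inf)), 0L)
})

test_that("a high-SNR spot is detected within one pixel of the truth", {
  set.seed(23)
  acq <- Acquisition(dim = c(32L, 32L), backgroundRate = 20)
  cell <- testCell(center = c(1.6, 1.6))
  em <- data.frame(a = 0.11, b = 0.05, c = 0, mode = "static",
                   state = "bright", channel = "A")
  img <- renderFrame(cell, em, noBleach(8000), acq)
  filt <- discoidalFilter(img)
  cand <- detectFoci(filt)
  expect_identical(nrow(cand), 1L)
  pos <- memloc:::cellToImage(cell, em$a, em$b)
  expect_lt(abs(cand$col - 1 + 0.5 - pos$x / 0.1), 1.5)
  expect_lt(abs(cand$row - 1 + 0.5 - pos$y / 0.1), 1.5)
})

test_that("the Gaussian fit recovers a noiseless pixel-centered spot exactly", {
  acq <- cleanAcq(dim = c(21L, 21L))
  cell <- testCell(center = c(1.05, 1.05))
  # emitter exactly at the center of pixel (11, 11)
  em <- data.frame(a = 0, b = 0, c = 0, mode = "static", state = "bright",
                   channel = "A")
  img <- renderFrame(cell, em, noBleach(5000), acq, noise = FALSE)
  f <- fitGaussianFocus(img, 11, 11)
  expect_false(is.null(f))
  expect_lt(abs(f$x - 1.05), 1e-4)
  expect_lt(abs(f$y - 1.05), 1e-4)
  # integrated volume close to the emitted mass
  expect_lt(abs(f$integrated_volume - 5000 * 0.034 * 30) /
              (5000 * 0.034 * 30), 0.02)
  # Gaussian identity between volume, amplitude and widths
  ps <- acq@pixelSize
  expect_equal(f$integrated_volume,
               2 * pi * f$amplitude * (f$width_x / ps) * (f$width_y / ps),
               tolerance = 1e-9)
})

test_that("fit uncertainty is consistent with the observed localization error", {
  set.seed(24)
  acq <- Acquisition(dim = c(21L, 21L), backgroundRate = 30)
  cell <- testCell(center = c(1.05, 1.05))
  em <- data.frame(a = 0.013, b = -0.021, c = 0, mode = "static",
                   state = "bright", channel = "A")
  pos <- memloc:::cellToImage(cell, em$a, em$b)
  fits <- list()
  for (i in 1:300) {
    img <- renderFrame(cell, em, noBleach(5000), acq)
    f <- fitGaussianFocus(img, 11, 11, emGain = acq@emGain,
                          readNoise = acq@readNoise)
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  fits <- do.call(rbind, fits)
  expect_gt(nrow(fits), 250)
  rmse <- sqrt(mean((fits$x - pos$x)^2))
  # claimed uncertainty within 35% of the realized error
  expect_lt(abs(rmse - mean(fits$sigma_x)) / rmse, 0.35)
  # and within a factor 2 of the photon-limited (Thompson) bound
  nph <- 5000 * 0.034
  thompson <- acq@psfSigma / sqrt(nph)
  expect_lt(rmse, 2 * sqrt(thompson^2 + acq@pixelSize^2 / 12 / nph +
                             8 * pi * acq@psfSigma^4 * 60^2 /
                             (acq@pixelSize^2 * nph^2)))
})

test_that("a candidate on flat background is discarded", {
  set.seed(25)
  img <- matrix(rnorm(21 * 21, 100, 3), 21, 21)
  expect_null(fitGaussianFocus(img, 11, 11))
  # and a window touching the border is discarded too
  expect_null(fitGaussianFocus(img, 2, 11))
})

test_that("super-resolution rendering conserves mass at any pixel size", {
  foci <- data.frame(x = c(0.52, 1.1, 0.8), y = c(0.61, 0.4, 1.2),
                     sigma_x = c(0.02, 0.05, 0.03),
                     sigma_y = c(0.03, 0.02, 0.04))
  img1 <- renderSuperres(foci, 0.01, c(160L, 160L))
  expect_lt(abs(sum(img1) - 3), 1e-3)
  img2 <- renderSuperres(foci[1, ], 0.025, c(64L, 64L))
  expect_lt(abs(sum(img2) - 1), 1e-3)
  expect_lt(abs(sum(img1) / 3 - sum(img2)), 2e-3)
  expect_true(all(renderSuperres(foci[0, ], 0.01, c(16L, 16L)) == 0))
})

test_that("location maps separate membrane from cytosolic populations", {
  set.seed(26)
  acq <- Acquisition(dim = c(56L, 24L), nFrames = 1L)
  std <- CellGeometry(center = c(0, 0), length = 3, width = 0.7)
  collectLS <- function(mode, nCells = 15) {
    out <- NULL
    for (i in seq_len(nCells)) {
      cell <- CellGeometry(center = c(1.2, 2.8), orientation = 0,
                          length = 4, width = 0.7)
      em <- seedEmitters(cell, mode, 6)
      img <- renderFrame(cell, em, noBleach(8000), acq)
      filt <- discoidalFilter(img)
      cand <- detectFoci(filt)
      if (nrow(cand) == 0) next
      fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(j)
        fitGaussianFocus(img, cand$row[j], cand$col[j])))
      if (is.null(fits)) next
      out <- rbind(out, cellCoordinates(fits$x, fits$y, cell))
    }
    out[complete.cases(out), ]
  }
  massOutside <- function(ls) {
    map <- locationMap(ls, std, nCells = 15, spotSigma = 0.035)
    img <- map$image
    # s coordinate of each map column (long axis is vertical on the map)
    sCol <- (seq_len(ncol(img)) - 0.5) * 0.02 + map$extent[1]
    outer <- abs(sCol) > 0.3 * std@width
    sum(img[, outer]) / sum(img)
  }
  lsMem <- collectLS("membrane")
  lsCyt <- collectLS("static")
  expect_gt(nrow(lsMem), 20)
  expect_gt(nrow(lsCyt), 20)
  expect_gt(massOutside(lsMem), 0.7)
  expect_lt(massOutside(lsCyt), 0.3)
  # doubling the identical foci set with doubled cell count is unchanged
  m1 <- locationMap(lsMem, std, nCells = 15)$image
  m2 <- locationMap(rbind(lsMem, lsMem), std, nCells = 30)$image
  expect_equal(m1, m2, tolerance = 1e-12)
})
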