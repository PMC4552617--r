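# Frame rendering and the EMCCD noise model.

test_that("an empty noiseless scene renders to the camera offset", {
  acq <- Acquisition(dim = c(16L, 16L), backgroundRate = 0,
                     autofluorRate = 0, readNoise = 0, offset = 100)
  img <- renderFrame(list(), list(), noBleach(), acq, noise = FALSE)
  expect_true(all(img == 100))
})

test_that("a single in-focus emitter renders at the right place with the right mass", {
  acq <- cleanAcq(dim = c(33L, 33L))
  cell <- testCell(center = c(1.65, 1.65))
  em <- data.frame(a = 0.07, b = -0.12, c = 0, mode = "static",
                   state = "bright", channel = "A")
  photo <- noBleach(photonRate = 5000)
  img <- renderFrame(cell, em, photo, acq, noise = FALSE)
  pos <- memloc:::cellToImage(cell, em$a, em$b)
  ij <- which(img == max(img), arr.ind = TRUE)
  expect_equal(ij[1, "col"], floor(pos$x / acq@pixelSize) + 1,
               ignore_attr = TRUE)
  expect_equal(ij[1, "row"], floor(pos$y / acq@pixelSize) + 1,
               ignore_attr = TRUE)
  # integrated signal: photons x gain, exact to 0.1% over a wide window
  expected <- 5000 * acq@frameInterval * acq@emGain
  expect_lt(abs(sum(img) - expected) / expected, 1e-3)
})

test_that("rendered intensity is linear in emitter count (noise off)", {
  acq <- cleanAcq(dim = c(32L, 32L))
  cell <- testCell()
  set.seed(9)
  em <- seedEmitters(cell, "static", 8)
  one <- renderFrame(cell, em[1, ], noBleach(), acq, noise = FALSE)
  all8 <- renderFrame(cell, em, noBleach(), acq, noise = FALSE)
  parts <- Reduce(`+`, lapply(1:8, function(i)
    renderFrame(cell, em[i, ], noBleach(), acq, noise = FALSE)))
  expect_equal(all8, parts, tolerance = 1e-12)
  expect_gt(sum(all8), 7.9 * sum(one))
})

test_that("the mean of many noisy renders matches the noiseless expectation", {
  acq <- Acquisition(dim = c(16L, 16L), backgroundRate = 30,
                     autofluorRate = 0, readNoise = 5, offset = 50)
  cell <- testCell(center = c(0.8, 0.8), length = 1.2, width = 0.6)
  em <- data.frame(a = 0, b = 0, c = 0, mode = "static", state = "bright",
                   channel = "A")
  expected <- renderFrame(cell, em, noBleach(), acq, noise = FALSE)
  set.seed(10)
  n <- 600
  acc <- 0
  for (i in seq_len(n))
    acc <- acc + renderFrame(cell, em, noBleach(), acq)
  meanImg <- acc / n
  # EMCCD noise SD per pixel ~ gain * sqrt(2 lambda) + read noise
  lam <- (expected - acq@offset) / acq@emGain
  sdPix <- sqrt(2 * lam * acq@emGain^2 + acq@readNoise^2) / sqrt(n)
  expect_lt(max(abs(meanImg - expected) / (sdPix + 1)), 5)
})

test_that("defocused emitters render wider and dimmer at constant mass", {
  acq <- cleanAcq(dim = c(33L, 33L))
  cell <- testCell(center = c(1.65, 1.65), width = 0.8)
  mk <- function(cc) data.frame(a = 0, b = 0, c = cc, mode = "static",
                                state = "bright", channel = "A")
  sharp <- renderFrame(cell, mk(0), noBleach(), acq, noise = FALSE)
  blurred <- renderFrame(cell, mk(0.3), noBleach(), acq, noise = FALSE)
  expect_gt(max(sharp), 2 * max(blurred))
  expect_lt(abs(sum(sharp) - sum(blurred)) / sum(sharp), 1e-3)
})

test_that("identical seeds give bit-identical stacks", {
  cell <- testCell()
  acq <- Acquisition(dim = c(24L, 24L), nFrames = 4L)
  run <- function() {
    set.seed(77)
    em <- seedEmitters(cell, "membrane", 10)
    simulateTimesampling(cell, em, Photophysics(), acq)$stack
  }
  expect_identical(frames(run()), frames(run()))
})
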