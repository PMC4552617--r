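# Image conditioning: illumination estimation, flat-fielding, discoidal
# filter, projections.

test_that("illumination estimation normalizes flat and uniform input", {
  flat <- array(500, c(32L, 32L, 4L))
  prof <- estimateIllumination(flat, blurRadius = 3)
  expect_equal(max(prof), 1)
  expect_lt(max(abs(prof - 1)), 1e-9)
  one <- matrix(250, 32, 32)
  expect_lt(max(abs(estimateIllumination(one, blurRadius = 3) - 1)), 1e-9)
  expect_error(estimateIllumination(list()))
})

test_that("the generating vignette is recovered from noisy movies", {
  set.seed(15)
  n <- 128L
  ill <- gaussianVignette(c(n, n), 0.7)
  movies <- lapply(1:6, function(i)
    array(ill, c(n, n, 5)) * 800 + rnorm(n * n * 5, 0, 20))
  # a modest blur keeps the reflect-padding bias at the corners small
  prof <- estimateIllumination(movies, blurRadius = 3)
  corners <- mean(prof[c(1, n, n * (n - 1) + 1, n * n)])
  expect_lt(abs(corners - 0.7), 0.02)
})

test_that("flatten divides by the profile and rejects zeros", {
  img <- matrix(runif(64, 1, 2), 8, 8)
  expect_equal(flatten(img, matrix(1, 8, 8)), img)
  prof <- matrix(runif(64, 0.5, 1), 8, 8)
  expect_equal(flatten(3 * prof, prof), matrix(3, 8, 8))
  expect_error(flatten(img, matrix(0, 8, 8)))
  expect_error(flatten(img, matrix(1, 4, 4)))
})

test_that("flat-fielding a vignetted render approximates the flat render", {
  set.seed(16)
  dim <- c(48L, 48L)
  ill <- gaussianVignette(dim, 0.7)
  cell <- testCell(center = c(2.4, 2.4))
  em <- seedEmitters(cell, "cytosolic", 10)
  acqV <- Acquisition(dim = dim, illumination = ill, readNoise = 0,
                      offset = 0)
  acqF <- Acquisition(dim = dim, readNoise = 0, offset = 0)
  imgV <- renderFrame(cell, em, noBleach(), acqV, noise = FALSE)
  imgF <- renderFrame(cell, em, noBleach(), acqF, noise = FALSE)
  corrected <- flatten(imgV, ill)
  expect_lt(mean(abs(corrected - imgF)), 0.02 * mean(imgF))
})

test_that("discoidal filter zeroes constants and preserves impulses", {
  expect_lt(max(discoidalFilter(matrix(7, 20, 20))), 1e-9)
  img <- matrix(0, 21, 21); img[11, 11] <- 1
  out <- discoidalFilter(img)
  expect_equal(which.max(out), which.max(img))
  expect_equal(out[1, 1], 0)
})

test_that("discoidal filter matches the brute-force kernel oracle", {
  set.seed(17)
  img <- matrix(runif(24 * 24, 0, 10), 24, 24)
  fast <- discoidalFilter(img, 1, 3)
  slow <- bruteDiscoidal(img, 1, 3)
  expect_equal(fast, slow, tolerance = 1e-8)
})

test_that("discoidal filter suppresses gradients but keeps peak location", {
  grad <- outer(seq(0, 5, length.out = 32), seq(0, 5, length.out = 32),
                "+")
  acq <- cleanAcq(dim = c(32L, 32L))
  cell <- testCell(center = c(1.6, 1.6))
  em <- data.frame(a = 0, b = 0, c = 0, mode = "static", state = "bright",
                   channel = "A")
  spot <- renderFrame(cell, em, noBleach(1000), acq, noise = FALSE)
  out <- discoidalFilter(spot + 20 * grad)
  expect_equal(which.max(out), which.max(spot))
  # background suppressed at least 10-fold relative to the peak
  far <- out[1:5, 28:32]
  expect_gt(max(out) / (max(far) + 1e-12), 10)
})

test_that("discoidal filter is translation-equivariant in the interior", {
  img <- matrix(0, 32, 32); img[10, 10] <- 5
  sh <- matrix(0, 32, 32); sh[14, 17] <- 5
  a <- discoidalFilter(img); b <- discoidalFilter(sh)
  expect_equal(a[6:14, 6:14], b[10:18, 13:21], tolerance = 1e-10)
})

test_that("average projection highlights static foci over mobile ones", {
  acq <- Acquisition(dim = c(32L, 32L), nFrames = 30L, backgroundRate = 20,
                     readNoise = 5)
  cell <- testCell(center = c(1.6, 1.6), length = 2.8, width = 0.8)
  set.seed(18)
  static <- seedEmitters(cell, "static", 1)
  mobile <- seedEmitters(cell, "cytosolic", 1)
  em <- rbind(static, mobile)
  sim <- simulateTimesampling(cell, em, noBleach(), acq)
  proj <- averageProjection(sim$stack)
  filtProj <- discoidalFilter(proj)
  posS <- memloc:::cellToImage(cell, static$a, static$b)
  iS <- floor(posS$y / acq@pixelSize) + 1
  jS <- floor(posS$x / acq@pixelSize) + 1
  # static focus survives projection with high contrast at its location
  expect_gt(filtProj[iS, jS], 0.5 * max(filtProj))
  # single-frame movie: projection is the identity
  one <- ImageStack(frames(sim$stack)[, , 1, drop = FALSE])
  expect_equal(averageProjection(one), frames(sim$stack)[, , 1])
  flatMovie <- array(3, c(8, 8, 5))
  expect_equal(averageProjection(flatMovie), matrix(3, 8, 8))
})
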