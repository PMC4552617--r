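# Track linking and static-focus selection.

test_that("an immobile spot links into one track spanning the movie", {
  foci <- data.frame(x = rep(1.0, 12) + rnorm(12, 0, 0.005),
                     y = rep(1.4, 12) + rnorm(12, 0, 0.005),
                     frame = 1:12)
  out <- linkTracks(foci, pixelSize = 0.1)
  expect_identical(length(unique(out$track)), 1L)
  ts <- trackSummary(out, frameInterval = 0.034)
  expect_identical(ts$nFoci, 12L)
  expect_equal(ts$duration, 12 * 0.034)
})

test_that("linking is empty on empty input and bridges single-frame gaps", {
  empty <- data.frame(x = numeric(0), y = numeric(0), frame = integer(0))
  expect_identical(nrow(linkTracks(empty)), 0L)
  gap <- data.frame(x = rep(1, 5), y = rep(1, 5), frame = c(1, 2, 4, 5, 6))
  out <- linkTracks(gap, pixelSize = 0.1, maxGap = 1)
  expect_identical(length(unique(out$track)), 1L)
  out2 <- linkTracks(gap, pixelSize = 0.1, maxGap = 0)
  expect_identical(length(unique(out2$track)), 2L)
})

test_that("distant spots never switch identity (3-frame toy vs expected assignment)", {
  # at frame 3 both spots reappear 0.35 um away from every track end,
  # beyond maxJump: both tracks must terminate and two new ones start
  foci <- data.frame(
    x = c(1.0, 2.0, 1.0, 2.0, 1.35, 1.65),
    y = rep(1, 6),
    frame = c(1, 1, 2, 2, 3, 3))
  out <- linkTracks(foci, pixelSize = 0.1, maxJump = 2, maxGap = 0)
  # frames 1-2 link straight (nearest neighbor at distance 0)
  t1 <- out$track[out$frame == 1 & out$x == 1.0]
  expect_identical(out$track[out$frame == 2 & out$x == 1.0], t1)
  # frame 3 positions are > 0.2 um from both track ends: new tracks
  expect_identical(length(unique(out$track)), 4L)
})

test_that("static-focus selection applies the persistence threshold strictly", {
  tracks <- data.frame(track = 1:3, start = c(1, 1, 5),
                       end = c(9, 8, 40), nFoci = c(9, 8, 36),
                       duration = c(9, 8, 36) * 0.034,
                       x = 0, y = 0)
  st <- staticFoci(tracks, minDuration = 0.300)
  # 9 frames x 34 ms = 306 ms > 300 ms; 8 frames = 272 ms is not static
  expect_identical(st$track, c(1L, 3L))
  expect_true(all(st$static))
})

test_that("static and mobile emitters are classified from a simulated movie", {
  set.seed(27)
  acq <- Acquisition(dim = c(64L, 64L), nFrames = 20L, backgroundRate = 20)
  cells <- list(testCell(center = c(1.6, 1.6), length = 3, width = 0.8),
                testCell(center = c(4.6, 1.6), length = 3, width = 0.8),
                testCell(center = c(1.6, 4.6), length = 3, width = 0.8),
                testCell(center = c(4.6, 4.6), length = 3, width = 0.8))
  emitters <- lapply(cells, function(cell) {
    # static (DNA-bound) molecules near the focal plane and mutually
    # resolvable, so every true static molecule is a detectable focus;
    # fast cytosolic molecules blur into background
    repeat {
      st <- seedEmitters(cell, "static", 2)
      if (abs(st$a[1] - st$a[2]) > 0.6) break
    }
    st$c <- runif(2, -0.1, 0.1)
    rbind(st, seedEmitters(cell, "cytosolic", 2))
  })
  sim <- simulateTimesampling(cells, emitters, noBleach(12000), acq)
  foci <- fitFociStack(sim$stack)
  out <- linkTracks(foci, pixelSize = 0.1)
  st <- staticFoci(trackSummary(out, 0.034))
  truth <- do.call(rbind, lapply(seq_along(cells), function(k) {
    em <- emitters[[k]]
    pos <- memloc:::cellToImage(cells[[k]], em$a, em$b)
    data.frame(x = pos$x, y = pos$y, mode = em$mode)
  }))
  staticTruth <- truth[truth$mode == "static", ]
  matched <- vapply(seq_len(nrow(staticTruth)), function(i)
    any(sqrt((st$x - staticTruth$x[i])^2 +
             (st$y - staticTruth$y[i])^2) < 0.15), logical(1))
  recall <- mean(matched)
  precision <- mean(vapply(seq_len(nrow(st)), function(i)
    any(sqrt((staticTruth$x - st$x[i])^2 +
             (staticTruth$y - st$y[i])^2) < 0.15), logical(1)))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})
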