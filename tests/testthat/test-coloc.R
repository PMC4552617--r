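# Two-channel colocalization and the Monte-Carlo chance baseline.

test_that("matching handles identical, displaced and empty inputs", {
  A <- data.frame(x = c(1, 2, 3), y = c(1, 1, 1))
  m <- matchFoci(A, A, radiusNm = 100)
  expect_equal(m$fraction, 1)
  expect_identical(nrow(m$pairs), 3L)
  B <- A; B$x <- B$x + 0.2     # 200 nm displacement, 2x the radius
  expect_equal(matchFoci(A, B, 100)$fraction, 0)
  expect_true(is.na(matchFoci(A, A[0, ], 100)$fraction))
  expect_equal(matchFoci(A[0, ], A, 100)$fraction, 0)
})

test_that("mutual-nearest-neighbor pairing equals the exhaustive optimal assignment", {
  set.seed(33)
  for (rep in 1:10) {
    # sparse toy: same-channel foci far apart so chains cannot form
    nA <- 5L; nB <- 5L
    A <- data.frame(x = runif(nA, 0, 4), y = runif(nA, 0, 4))
    while (nrow(A) > 1 && min(dist(A)) < 0.25)
      A <- data.frame(x = runif(nA, 0, 4), y = runif(nA, 0, 4))
    B <- A + matrix(rnorm(2 * nA, 0, 0.06), ncol = 2)
    colnames(B) <- c("x", "y")
    m <- matchFoci(A, B, radiusNm = 100)
    oracle <- bruteMatch(A, B, radiusNm = 100)
    expect_identical(nrow(m$pairs), oracle$n)
    if (nrow(m$pairs)) {
      got <- m$pairs[order(m$pairs$b), c("a", "b")]
      want <- oracle$pairs[order(oracle$pairs$b), ]
      expect_equal(got$a, want$a, ignore_attr = TRUE)
    }
  }
})

test_that("the chance baseline approaches its limits and the area ratio", {
  set.seed(34)
  cell <- testCell(length = 3, width = 0.8, center = c(1.6, 1.6))
  fociA <- data.frame(cell = 1, x = c(1.4, 1.9), y = c(1.0, 2.2))
  # vanishing radius: no chance pairing
  tiny <- chanceBaseline(cell, fociA, nBPerCell = 2, radiusNm = 0.1,
                         nDraws = 50)
  expect_lt(tiny$baseline, 0.01)
  # an A focus at every position: every draw pairs
  dense <- do.call(rbind, lapply(seq(0.4, 2.8, by = 0.1), function(a) {
    p <- memloc:::cellToImage(cell, a - 1.6, 0)
    data.frame(cell = 1, x = p$x, y = p$y)
  }))
  full <- chanceBaseline(cell, dense, nBPerCell = 2, radiusNm = 400,
                         nDraws = 50)
  expect_gt(full$baseline, 0.95)
  # two well-separated foci at 100 nm: Monte-Carlo matches the capture-area
  # ratio (2 pi r^2 over the projected footprint area) and stays below 10%
  mc <- chanceBaseline(cell, fociA, nBPerCell = 2, radiusNm = 100,
                       nDraws = 800)
  analytic <- 2 * pi * 0.1^2 / memloc:::footprintArea(cell)
  expect_lt(abs(mc$baseline - analytic), 2 * mc$se + 0.005)
  expect_lt(mc$baseline, 0.10)
})

test_that("per-cell statistics aggregate over cells", {
  pc <- data.frame(nA = c(2, 2, 2), nB = c(2, 2, 2),
                   fraction = c(0.5, 0.5, 0.5))
  st <- perCellStats(pc, chance = 0.05)
  expect_equal(st$sem, 0)
  expect_equal(st$fraction, 0.5)
  pcNA <- data.frame(nA = 1, nB = 0, fraction = NA_real_)
  expect_true(is.na(perCellStats(pcNA)$fraction))
})

test_that("generated colocalized fractions are recovered from ground truth", {
  set.seed(35)
  acq <- Acquisition(dim = c(160L, 160L), nFrames = 1L)
  cells <- layoutCells(30, acq, length = 3, width = 0.8, minSep = 1.6)
  for (f in c(0, 0.27, 1)) {
    sim <- simulateTwoChannel(cells, nA = 2, nB = 2, colocFraction = f,
                              offsetSdNm = 25, acq = acq)
    pairs <- truthPairs(sim$truth)
    fA <- sim$fociA
    fracs <- vapply(seq_along(cells), function(k) {
      A <- fA[fA$cell == k, c("x", "y")]
      B <- pairs[pairs$cell == k, c("xB", "yB")]
      names(B) <- c("x", "y")
      matchFoci(A, B, radiusNm = 100)$fraction
    }, numeric(1))
    est <- mean(fracs)
    chance <- chanceBaseline(cells, fA, nBPerCell = 2, radiusNm = 100,
                             nDraws = 60)$baseline
    target <- f + (1 - f) * chance
    n <- 2 * length(cells)
    binomSe <- sqrt(max(target * (1 - target), 0.01) / n)
    expect_lt(abs(est - target), 3 * binomSe + 0.02)
  }
})
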