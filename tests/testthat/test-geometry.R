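# Spherocylinder geometry: emitter seeding, masks, coordinates, volumes.

test_that("membrane emitters lie on the spherocylinder surface", {
  set.seed(1)
  cell <- testCell(length = 4, width = 0.6)
  em <- seedEmitters(cell, "membrane", 500)
  h <- (cell@length - cell@width) / 2
  # cylindrical section: radial distance from the long axis is exactly w/2
  cyl <- abs(em$a) <= h
  expect_true(sum(cyl) > 0)
  rad <- sqrt(em$b[cyl]^2 + em$c[cyl]^2)
  expect_equal(rad, rep(0.3, sum(cyl)), tolerance = 1e-12)
  # caps: distance from the cap center is w/2
  cap <- !cyl
  radCap <- sqrt((abs(em$a[cap]) - h)^2 + em$b[cap]^2 + em$c[cap]^2)
  expect_equal(radCap, rep(0.3, sum(cap)), tolerance = 1e-12)
})

test_that("cytosolic emitters fill the volume uniformly", {
  set.seed(2)
  cell <- testCell(length = 4, width = 0.6)
  em <- seedEmitters(cell, "cytosolic", 1e5)
  expect_true(all(memloc:::insideSpherocylinder(em$a, em$b, em$c, cell)))
  # in the cylindrical section the transverse position is uniform on a
  # disk: mean radial distance is 2r/3 (analytic)
  h <- (cell@length - cell@width) / 2
  cyl <- abs(em$a) <= h
  rad <- sqrt(em$b[cyl]^2 + em$c[cyl]^2)
  se <- sd(rad) / sqrt(sum(cyl))
  expect_lt(abs(mean(rad) - 2 * 0.3 / 3), 4 * se)
})

test_that("seeding zero emitters or an unknown mode is handled", {
  cell <- testCell()
  expect_identical(nrow(seedEmitters(cell, "membrane", 0)), 0L)
  expect_error(seedEmitters(cell, "nuclear", 5))
})

test_that("mask area matches the analytic footprint", {
  acq <- cleanAcq(dim = c(64L, 64L))
  cell <- testCell(length = 4, width = 0.8, center = c(3.2, 3.2))
  mask <- makeMask(cell, acq)
  areaPx <- sum(mask)
  analytic <- memloc:::footprintArea(cell) / acq@pixelSize^2
  # pixelation error bounded by the perimeter in pixels
  perim <- (2 * (cell@length - cell@width) + pi * cell@width) /
    acq@pixelSize
  expect_lt(abs(areaPx - analytic), perim)
  # a vanishingly thin cell gives an empty mask
  thin <- CellGeometry(center = c(3.2, 3.2), length = 4, width = 0.004)
  expect_equal(sum(makeMask(thin, acq)), 0)
})

test_that("mask of several cells is the union of the single-cell masks", {
  acq <- cleanAcq(dim = c(64L, 64L))
  c1 <- testCell(center = c(1.6, 1.6))
  c2 <- testCell(center = c(4.6, 4.6))
  expect_identical(makeMask(list(c1, c2), acq),
                   makeMask(c1, acq) | makeMask(c2, acq))
})

test_that("cell coordinates normalize and invert exactly", {
  cell <- CellGeometry(center = c(2.1, 3.3), orientation = 0.3,
                       length = 3.5, width = 0.7)
  expect_equal(unlist(cellCoordinates(2.1, 3.3, cell)), c(l = 0, s = 0))
  # membrane midpoint maps to s = +/- 1/2
  ax <- memloc:::cellAxes(cell)
  p <- cell@center + 0.35 * ax$v
  cs <- cellCoordinates(p[1], p[2], cell)
  expect_equal(cs$s, 0.5, tolerance = 1e-9)
  # round trip over random interior points
  set.seed(3)
  em <- seedEmitters(cell, "cytosolic", 50)
  pos <- memloc:::cellToImage(cell, em$a, em$b)
  cs <- cellCoordinates(pos$x, pos$y, cell)
  back <- memloc:::cellCoordinatesInverse(cs$l, cs$s, cell)
  expect_lt(max(abs(back$x - pos$x)), 1e-6)
  expect_lt(max(abs(back$y - pos$y)), 1e-6)
  # positions outside the footprint are excluded
  far <- cellCoordinates(cell@center[1] + 5, cell@center[2], cell)
  expect_true(is.na(far$l))
})

test_that("cell volume from a mask matches the analytic spherocylinder", {
  acq <- cleanAcq(dim = c(80L, 80L), pixelSize = 0.05)
  cell <- testCell(length = 3, width = 0.8, center = c(2, 2))
  v <- cellVolume(makeMask(cell, acq), acq@pixelSize)
  expect_lt(abs(v$volume - spherocylinderVolume(3, 0.8)) /
              spherocylinderVolume(3, 0.8), 0.05)
  expect_lt(abs(v$length - 3), 0.1)
  expect_lt(abs(v$width - 0.8), 0.08)
  # degenerate masks are rejected
  expect_error(cellVolume(matrix(FALSE, 4, 4), 0.1))
  thin <- matrix(FALSE, 20, 20); thin[5:15, 10] <- TRUE
  expect_error(cellVolume(thin, 0.1), "thinner")
})

test_that("spherocylinder volume reduces to a sphere when L = w", {
  expect_equal(spherocylinderVolume(0.8, 0.8), (4 / 3) * pi * 0.4^3)
})
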