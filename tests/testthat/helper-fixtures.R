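# Shared fixture builders for the test suite. All simulation inputs are
# generated in code under fixed seeds; no data files.

# Small, quiet acquisition for unit tests: no camera noise unless asked.
cleanAcq <- function(dim = c(32L, 32L), nFrames = 1L, ...) {
  Acquisition(dim = dim, nFrames = nFrames, backgroundRate = 0,
              autofluorRate = 0, readNoise = 0, offset = 0, ...)
}

# A single vertical cell centered in a small field.
testCell <- function(length = 3, width = 0.6, center = c(1.6, 1.6),
                     orientation = 0) {
  CellGeometry(center = center, orientation = orientation,
               length = length, width = width)
}

noBleach <- function(photonRate = 5000) {
  Photophysics(bleachTau = Inf, darkRate = 0, returnRate = 0,
               photonRate = photonRate)
}

# Brute-force reference for the binned short-axis correlation statistic:
# plain loops, median-subtracted bin profiles, unbiased overlap scaling.
bruteCorrelation <- function(imgA, imgB, maxLag, binHeight, pixelSize) {
  binRows <- max(1L, round(binHeight / pixelSize))
  if (binRows > nrow(imgA)) binRows <- nrow(imgA)
  K <- round(maxLag / pixelSize)
  nBins <- max(1L, nrow(imgA) %/% binRows)
  acc <- numeric(2 * K + 1)
  for (b in seq_len(nBins)) {
    r0 <- (b - 1) * binRows + 1
    r1 <- if (b == nBins) nrow(imgA) else b * binRows
    p <- colMeans(imgA[r0:r1, , drop = FALSE])
    q <- colMeans(imgB[r0:r1, , drop = FALSE])
    p <- p - median(p); q <- q - median(q)
    n <- length(p)
    for (ki in seq(-K, K)) {
      s <- 0; cnt <- 0
      for (i in seq_len(n)) {
        j <- i + ki
        if (j >= 1 && j <= n) { s <- s + p[i] * q[j]; cnt <- cnt + 1 }
      }
      acc[ki + K + 1] <- acc[ki + K + 1] + s / cnt
    }
  }
  acc / nBins
}

# Brute-force discoidal filter with reflect padding: direct double loop.
bruteDiscoidal <- function(img, rInner, rOuter) {
  r <- ceiling(rOuter)
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) {
    # reflect indices (edge pixel not duplicated), matching pad-and-crop
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  idx <- -r:r
  d <- sqrt(outer(idx^2, idx^2, "+"))
  disk <- d <= rInner
  ann <- d > rInner & d <= rOuter
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- matrix(0, 2 * r + 1, 2 * r + 1)
    for (a in idx) for (b in idx)
      vals[a + r + 1, b + r + 1] <- img[refl(i + a, nr), refl(j + b, nc)]
    out[i, j] <- mean(vals[disk]) - mean(vals[ann])
  }
  pmax(out, 0)
}

# Exhaustive optimal matching oracle: maximize the number of pairs within
# the cap, break ties by minimal total distance. Feasible for small sets.
bruteMatch <- function(A, B, radiusNm) {
  cap <- radiusNm / 1000
  nA <- nrow(A); nB <- nrow(B)
  d <- sqrt(outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2)
  best <- list(n = -1L, dist = Inf, pairs = NULL)
  recurse <- function(b, used, pairs, tot) {
    if (b > nB) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && tot < best$dist))
        best <<- list(n = n, dist = tot, pairs = pairs)
      return(invisible())
    }
    recurse(b + 1L, used, pairs, tot)              # leave b unmatched
    for (a in seq_len(nA)) {
      if (!used[a] && d[a, b] <= cap) {
        used[a] <- TRUE
        recurse(b + 1L, used, rbind(pairs, data.frame(a = a, b = b)),
                tot + d[a, b])
        used[a] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nA), data.frame(a = integer(0), b = integer(0)), 0)
  best
}
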