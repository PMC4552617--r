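# Short-axis autocorrelation / cross-correlation localization statistic.
#
# The statistic conceptually duplicates an image, shifts the duplicate
# sideways by a distance lag and measures the correlation of pixel values
# against the original. Membrane-associated signal in vertically oriented
# rod cells produces secondary correlation peaks at a lag equal to the cell
# width; cytosolic signal produces a single broad origin peak.

# Average rows of an image within vertical bins of `binRows` rows, giving
# one horizontal profile per bin.
binProfiles <- function(image, binRows) {
  nr <- nrow(image)
  nBins <- max(1L, nr %/% binRows)
  lapply(seq_len(nBins), function(b) {
    r0 <- (b - 1L) * binRows + 1L
    r1 <- if (b == nBins) nr else b * binRows
    colMeans(image[r0:r1, , drop = FALSE])
  })
}

# Raw lag products of two equal-length profiles at lags -K..K, divided by
# the overlap length (unbiased scaling, so finite image width does not
# taper the function toward large lags).
profileCrossCorr <- function(p, q, K) {
  n <- length(p)
  K <- min(K, n - 1L)
  ks <- -K:K
  vapply(ks, function(k) {
    if (k >= 0) sum(p[1:(n - k)] * q[(1 + k):n]) / (n - k)
    else sum(p[(1 - k):n] * q[1:(n + k)]) / (n + k)
  }, numeric(1))
}

# Shared engine: bin rows, correlate profiles, average over bins and over
# frames of a stack.
imageCorrelation <- function(imageA, imageB, maxLag, binHeight, pixelSize,
                             type) {
  getFrames <- function(x) {
    if (is(x, "ImageStack")) frames(x)
    else if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
  }
  a <- getFrames(imageA); b <- getFrames(imageB)
  if (!identical(dim(a), dim(b))) stop("image dimensions must match")
  binRows <- max(1L, round(binHeight / pixelSize))
  if (binRows > dim(a)[1L]) {
    warning("bin height exceeds image height; using a single bin")
    binRows <- dim(a)[1L]
  }
  K <- round(maxLag / pixelSize)
  if (K > dim(a)[2L] - 1L) stop("max lag exceeds image width")
  acc <- NULL; n <- 0L
  for (t in seq_len(dim(a)[3L])) {
    pa <- binProfiles(a[, , t], binRows)
    pb <- binProfiles(b[, , t], binRows)
    for (i in seq_along(pa)) {
      # subtract the profile median before the lag products: clipping the
      # peak filter at zero leaves a positive DC level that would turn
      # into a flat pedestal across all lags; the median estimates that
      # level robustly without eating compact cell structure in narrow
      # single-cell crops
      cc <- profileCrossCorr(pa[[i]] - stats::median(pa[[i]]),
                             pb[[i]] - stats::median(pb[[i]]), K)
      acc <- if (is.null(acc)) cc else acc + cc
      n <- n + 1L
    }
  }
  CorrelationFunction(lags = (-K:K) * pixelSize, values = acc / n,
                      type = type)
}

#' Image-wide short-axis autocorrelation
#'
#' Averages the image rows within vertical bins (default 20 um tall), takes
#' the spatial autocorrelation of each bin's median-subtracted horizontal
#' profile at integer-pixel lags up to \code{maxLag}, and averages the
#' per-bin functions (and per-frame functions, for a stack). Images should
#' be peak-filtered (\code{\link{discoidalFilter}}) first; each bin
#' profile's median is subtracted before the lag products to remove the
#' residual DC level that the filter's clipping at zero leaves behind,
#' which would otherwise appear as a flat pedestal across all lags.
#'
#' @param image matrix, 3D array or \code{\link{ImageStack}} of
#'   peak-filtered fluorescence data.
#' @param maxLag maximum distance lag (um, default 1).
#' @param binHeight vertical bin height (um, default 20).
#' @param pixelSize um per pixel; defaults to the \code{ImageStack}
#'   calibration, else 0.1.
#' @return a \code{\link{CorrelationFunction}}, even in the lag.
#' @export
rowAutocorrelation <- function(image, maxLag = 1, binHeight = 20,
                               pixelSize = NULL) {
  if (is.null(pixelSize))
    pixelSize <- if (is(image, "ImageStack")) image@pixelSize else 0.1
  imageCorrelation(image, image, maxLag, binHeight, pixelSize, "auto")
}

#' Two-channel short-axis cross-correlation
#'
#' Same binning and lag products as \code{\link{rowAutocorrelation}}, but
#' correlating the horizontal profiles of one channel against the other; no
#' intensity normalization is applied. Colocalized membrane signal in both
#' channels produces sharp peaks at lag 0 and at plus/minus the cell width.
#'
#' @param imageA,imageB same-shape images/stacks of the two channels.
#' @param maxLag,binHeight,pixelSize as in \code{\link{rowAutocorrelation}}.
#' @return a \code{\link{CorrelationFunction}} of type "cross".
#' @export
crossCorrelation <- function(imageA, imageB, maxLag = 1, binHeight = 20,
                             pixelSize = NULL) {
  if (is.null(pixelSize))
    pixelSize <- if (is(imageA, "ImageStack")) imageA@pixelSize else 0.1
  imageCorrelation(imageA, imageB, maxLag, binHeight, pixelSize, "cross")
}

#' Normalize a correlation time course
#'
#' Divides the correlation function of each time point by the mean cellular
#' fluorescence intensity I of that time point, then rescales the whole
#' time x lag matrix so its maximal zero-lag value equals 1. The zero-lag
#' amplitude of the normalized course then tracks the relative cellular
#' protein concentration over time.
#'
#' @param cfs list of \code{\link{CorrelationFunction}}, one per time point
#'   (identical lag axes).
#' @param intensities numeric, mean cellular fluorescence per time point.
#' @param times numeric, time of each point (minutes).
#' @return a \code{\link{CorrelationTimecourse}} with normalization tag
#'   "zero-lag-max-one".
#' @export
normalizeTimecourse <- function(cfs, intensities, times = seq_along(cfs)) {
  stopifnot(length(cfs) == length(intensities),
            length(cfs) == length(times))
  lag0 <- lags(cfs[[1]])
  mat <- t(vapply(cfs, function(cf) {
    stopifnot(identical(lags(cf), lag0))
    values(cf)
  }, numeric(length(lag0))))
  pos <- intensities > 0
  mat[pos, ] <- mat[pos, , drop = FALSE] / intensities[pos]
  mat[!pos, ] <- 0
  top <- max(mat)
  if (top <= 0) stop("all correlation values are zero; cannot normalize")
  mat <- mat / top
  new("CorrelationTimecourse", times = as.numeric(times), lags = lag0,
      values = mat, normalization = "zero-lag-max-one")
}

# Morphological opening (rolling minimum then rolling maximum, half-width
# hw points): a lower envelope that follows structures wider than ~2 hw and
# passes under narrower peaks; used as a local baseline.
rollingOpen <- function(v, hw) {
  n <- length(v)
  roll <- function(x, f) vapply(seq_len(n), function(i)
    f(x[max(1, i - hw):min(n, i + hw)]), numeric(1))
  roll(roll(v, min), max)
}

#' Secondary (off-origin) peaks of a correlation function
#'
#' Finds local maxima with |lag| greater than an exclusion zone around the
#' origin, refines each position sub-pixel by a 3-point parabola, discards
#' maxima smaller than \code{minHeight} times the zero-lag value (noise
#' wiggles), and merges symmetric +/- pairs into a single |lag|. A
#' secondary lobe rides on the decaying flank of the origin peak plus any
#' broad pedestal from uncorrelated structure, which drags a naive maximum
#' inward; a local baseline estimated by morphological opening (rolling
#' minimum then maximum over \code{baselineHalfWidth} lag samples) is
#' therefore subtracted before the maxima are located and refined. Set
#' \code{baselineHalfWidth = 0} to disable the correction.
#'
#' @param cf a \code{\link{CorrelationFunction}}.
#' @param exclusion half-width of the origin exclusion zone (um,
#'   default 0.25).
#' @param minHeight minimum peak height as a fraction of the zero-lag
#'   value, measured on the baseline-subtracted function (default 0.02).
#' @param baselineHalfWidth half-width of the opening window in lag
#'   samples (0 disables the baseline correction, default).
#' @param refine "parabola" (3-point interpolation at each maximum) or
#'   "decompose" (the symmetric pair is refined by fitting the whole
#'   function as a central Gaussian plus a symmetric side-peak pair plus a
#'   constant, which is insensitive to the flank of the origin peak under
#'   the side lobe; falls back to the parabola when the fit fails).
#' @return numeric vector of |lag| positions (um), strongest first; empty
#'   when there is no secondary structure.
#' @export
secondaryPeaks <- function(cf, exclusion = 0.25, minHeight = 0.02,
                           baselineHalfWidth = 0L,
                           refine = c("parabola", "decompose")) {
  refine <- match.arg(refine)
  stopifnot(exclusion > 0)
  lag <- lags(cf); v <- values(cf)
  n <- length(v)
  if (n < 3L) return(numeric(0))
  v0 <- v[which.min(abs(lag))]
  if (baselineHalfWidth > 0) v <- v - rollingOpen(v, baselineHalfWidth)
  i <- 2:(n - 1)
  isMax <- v[i] > v[i - 1] & v[i] >= v[i + 1]
  cand <- i[isMax & abs(lag[i]) > exclusion &
              v[i] >= minHeight * max(v0, max(v))]
  if (length(cand) == 0L) return(numeric(0))
  dlag <- lag[2] - lag[1]
  refined <- vapply(cand, function(j) {
    denom <- v[j - 1] - 2 * v[j] + v[j + 1]
    d <- if (abs(denom) > .Machine$double.eps)
      0.5 * (v[j - 1] - v[j + 1]) / denom else 0
    lag[j] + max(min(d, 0.5), -0.5) * dlag
  }, numeric(1))
  heights <- v[cand]
  absLag <- abs(refined)
  ord <- order(-heights)
  absLag <- absLag[ord]; heights <- heights[ord]
  out <- numeric(0); outH <- numeric(0)
  for (i in seq_along(absLag)) {
    near <- which(abs(out - absLag[i]) < 0.6 * dlag)
    if (length(near)) {
      j <- near[1]
      out[j] <- (out[j] * outH[j] + absLag[i] * heights[i]) /
        (outH[j] + heights[i])
      outH[j] <- outH[j] + heights[i]
    } else {
      out <- c(out, absLag[i]); outH <- c(outH, heights[i])
    }
  }
  out <- out[order(-outH)]
  if (refine == "decompose" && length(out)) {
    d <- refinePairDecompose(lags(cf), values(cf), out[1])
    if (!is.na(d)) out[1] <- d
  }
  out
}

# Refine the dominant symmetric side-peak position by decomposing the
# correlation function into a generalized-Gaussian origin peak (whose
# exponent absorbs the heavy flank that a plain Gaussian underfits), a
# symmetric Gaussian side-peak pair, and a constant.
refinePairDecompose <- function(lag, v, d0) {
  i0 <- which.min(abs(lag))
  sel <- abs(abs(lag) - d0) < 2.5 * (lag[2] - lag[1])
  df <- data.frame(lag = lag, v = v)
  start <- list(A0 = v[i0], a = max(d0 / 4, 0.1), p = 1.5,
                A1 = max(v[sel]), d = d0, s1 = max(d0 / 6, 0.06), c = 0)
  fit <- tryCatch(minpack.lm::nlsLM(
    v ~ A0 * exp(-(abs(lag) / a)^p) +
      A1 * (exp(-(lag - d)^2 / (2 * s1^2)) +
            exp(-(lag + d)^2 / (2 * s1^2))) + c,
    data = df, start = start,
    lower = c(A0 = 0, a = 0.02, p = 0.8, A1 = 0, d = 0.6 * d0,
              s1 = 0.02, c = -Inf),
    upper = c(A0 = Inf, a = max(lag), p = 4, A1 = Inf,
              d = min(1.4 * d0, max(lag)), s1 = max(lag) / 2, c = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  cfp <- stats::coef(fit)
  if (cfp[["A1"]] <= 0) return(NA_real_)
  cfp[["d"]]
}

#' Membrane-association score of a correlation function
#'
#' Ratio of the mean correlation value at lags within
#' \code{expectedWidth +/- tol} (both signs) to the zero-lag value, clipped
#' to [0, 1]. Membrane-associated signal concentrates correlation mass at
#' the cell width and scores high; cytosolic signal decays before the cell
#' width and scores low. Automates the visual membrane/cytosolic call.
#'
#' @param cf a \code{\link{CorrelationFunction}}.
#' @param expectedWidth expected cell width (um).
#' @param tol half-width of the lag window (um, > 0; default 0.1).
#' @return a scalar in [0, 1].
#' @export
membraneScore <- function(cf, expectedWidth, tol = 0.1) {
  stopifnot(tol > 0)
  lag <- lags(cf); v <- values(cf)
  v0 <- v[which.min(abs(lag))]
  if (v0 <= 0) return(0)
  sel <- abs(abs(lag) - expectedWidth) <= tol
  if (!any(sel)) return(0)
  max(min(mean(v[sel]) / v0, 1), 0)
}

#' Mean intensity inside a mask
#'
#' Mean pixel value within a cell mask, per frame for a stack; the
#' intensity I used to normalize correlation time courses.
#'
#' @param image matrix, 3D array or \code{\link{ImageStack}}.
#' @param mask logical matrix.
#' @return numeric scalar (matrix input) or vector (one value per frame).
#' @export
meanCellIntensity <- function(image, mask) {
  a <- if (is(image, "ImageStack")) frames(image) else image
  if (is.matrix(a)) return(mean(a[mask]))
  apply(a, 3L, function(f) mean(f[mask]))
}
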