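# Single-molecule intensity calibrations: late-movie dark-state returns and
# change-point photobleaching step sizes.

#' Single-molecule intensity from late-movie returns
#'
#' Late in a movie most of the cellular fluorescence has bleached, but
#' individual molecules occasionally return from a dark state and appear as
#' isolated foci. Detecting and Gaussian-fitting the foci of the final
#' \code{tailFrames} frames and averaging their integrated volumes yields
#' the fluorescence signal of one molecule in one frame. Only isolated
#' foci enter the average (overlapping spots bias the fitted amplitudes).
#'
#' @param movie an \code{\link{ImageStack}}.
#' @param tailFrames number of final frames to examine (default 50).
#' @param psfSigma nominal PSF sigma (um).
#' @param threshold detection threshold (default per frame,
#'   \code{\link{detectionThreshold}}).
#' @param minIsolation only foci at least this many pixels away from any
#'   other candidate are used (default 8), so overlapping molecules do not
#'   bias the calibration.
#' @param ... further arguments to \code{\link{fitFociStack}}.
#' @return an \code{\link{SMCalibration}} with source "returns"; flagged
#'   low-confidence when fewer than 10 foci were observed.
#' @export
smIntensityFromReturns <- function(movie, tailFrames = 50, psfSigma = 0.10,
                                   threshold = NULL, minIsolation = 8, ...) {
  nT <- nFrames(movie)
  tail <- max(nT - tailFrames + 1L, 1L):nT
  foci <- fitFociStack(movie, psfSigma = psfSigma, threshold = threshold,
                       frames = tail, minIsolation = minIsolation, ...)
  n <- nrow(foci)
  if (n == 0L)
    return(SMCalibration(unitIntensity = NA_real_, source = "returns",
                         nObservations = 0L, flagged = TRUE))
  SMCalibration(unitIntensity = mean(foci$integrated_volume),
                source = "returns", nObservations = n, flagged = n < 10L)
}

# l2-cost binary segmentation. Recursively split where the split reduces
# the residual sum of squares by more than `penalty`; returns changepoint
# indices (last index of each segment except the final one).
binarySegment <- function(x, penalty, minSize = 2L) {
  n <- length(x)
  splitGain <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2L * minSize) return(c(NA_real_, NA_integer_))
    seg <- x[lo:hi]
    cs <- cumsum(seg); css <- cumsum(seg^2)
    tot <- css[m] - cs[m]^2 / m
    ks <- minSize:(m - minSize)
    left <- css[ks] - cs[ks]^2 / ks
    right <- (css[m] - css[ks]) - (cs[m] - cs[ks])^2 / (m - ks)
    gain <- tot - (left + right)
    i <- which.max(gain)
    c(gain[i], lo + ks[i] - 1L)
  }
  cps <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue)) {
    seg <- queue[[1]]; queue <- queue[-1]
    g <- splitGain(seg[1], seg[2])
    if (!is.na(g[1]) && g[1] > penalty) {
      k <- as.integer(g[2])
      cps <- c(cps, k)
      queue <- c(queue, list(c(seg[1], k)), list(c(k + 1L, seg[2])))
    }
  }
  sort(cps)
}

#' Photobleaching step sizes by change-point analysis
#'
#' Segments the locally background-subtracted intensity trace of a static
#' focus into piecewise-constant levels by l2-cost binary segmentation with
#' a BIC-style penalty, and returns the level differences at downward
#' transitions: the sizes of single-molecule photobleaching steps. The
#' penalty is \code{penaltyFactor * sigma^2 * log(n)} with the noise SD
#' estimated robustly from first differences (MAD / sqrt(2)); the factor
#' was calibrated once on noiseless and noisy staircase fixtures so that a
#' monotone ramp is not over-segmented.
#'
#' @param trace numeric intensity trace of one focus.
#' @param penalty segmentation penalty; by default computed from the trace.
#' @param penaltyFactor multiplier of the BIC-style penalty (default 6).
#' @param minSize minimum segment length in frames (default 2).
#' @return list with \code{steps} (positive sizes of down-steps, possibly
#'   empty), \code{levels} (segment means), \code{changepoints} (last index
#'   of each segment but the final).
#' @export
stepSizesChangepoint <- function(trace, penalty = NULL, penaltyFactor = 6,
                                 minSize = 2L) {
  n <- length(trace)
  if (n < 2L * minSize)
    return(list(steps = numeric(0), levels = mean(trace),
                changepoints = integer(0)))
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(trace)) / sqrt(2)
    sigma <- max(sigma, 1e-12)
    penalty <- penaltyFactor * sigma^2 * log(n)
  }
  cps <- binarySegment(trace, penalty, minSize)
  bounds <- c(0L, cps, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(trace[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  d <- diff(levels)
  list(steps = -d[d < 0], levels = levels, changepoints = cps)
}

#' Single-molecule intensity from step-size histogram
#'
#' Pools photobleaching step sizes from many static-focus traces and takes
#' the mode of their distribution (kernel density peak) as the unit
#' intensity of one molecule.
#'
#' @param traces list of numeric traces (or a single one).
#' @param ... arguments passed to \code{\link{stepSizesChangepoint}}.
#' @return an \code{\link{SMCalibration}} with source "steps".
#' @export
smIntensityFromSteps <- function(traces, ...) {
  if (is.numeric(traces)) traces <- list(traces)
  steps <- unlist(lapply(traces, function(tr)
    stepSizesChangepoint(tr, ...)$steps))
  n <- length(steps)
  if (n == 0L)
    return(SMCalibration(unitIntensity = NA_real_, source = "steps",
                         nObservations = 0L, flagged = TRUE))
  unit <- if (n >= 5L) {
    d <- stats::density(steps)
    d$x[which.max(d$y)]
  } else stats::median(steps)
  SMCalibration(unitIntensity = unit, source = "steps",
                nObservations = n, flagged = n < 10L)
}

#' Intensity trace of a focus with local background subtraction
#'
#' Integrated intensity in a disk around a fixed position, minus the
#' per-pixel median of a surrounding annulus times the disk area, per
#' frame: the photobleaching trace of a static focus.
#'
#' @param movie an \code{\link{ImageStack}} or 3D array.
#' @param row,col 1-based pixel indices of the focus.
#' @param rDisk integration radius (px, default 3).
#' @param rAnnulus outer radius of the background annulus (px, default 6).
#' @return numeric vector, one value per frame.
#' @export
focusTrace <- function(movie, row, col, rDisk = 3, rAnnulus = 6) {
  a <- if (is(movie, "ImageStack")) frames(movie) else movie
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  nr <- dim(a)[1]; nc <- dim(a)[2]
  ii <- max(1, row - rAnnulus):min(nr, row + rAnnulus)
  jj <- max(1, col - rAnnulus):min(nc, col + rAnnulus)
  d <- sqrt(outer((ii - row)^2, (jj - col)^2, "+"))
  disk <- d <= rDisk
  ann <- d > rDisk & d <= rAnnulus
  vapply(seq_len(dim(a)[3L]), function(t) {
    w <- a[ii, jj, t]
    sum(w[disk]) - stats::median(w[ann]) * sum(disk)
  }, numeric(1))
}
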