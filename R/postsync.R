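# Burst classification, post-synchronization to peak intensity, and
# three-phase segmentation of single-cell trajectories.

#' Classify the burst structure of a single-cell trajectory
#'
#' A trajectory is classed \code{"none"} when its maximum does not rise
#' above the noise floor (median + \code{noiseMult} robust SDs of the
#' early, pre-onset portion of the trace), \code{"single"} when exactly one
#' contiguous epoch exceeds \code{relThreshold} times the maximum, and
#' \code{"multiple"} otherwise. Only single-burst cells can be
#' post-synchronized to their intensity peak.
#'
#' @param values background-corrected cell intensities over time.
#' @param relThreshold epoch threshold as a fraction of the maximum
#'   (default 0.5).
#' @param noiseMult noise-floor multiplier (default 3).
#' @param baselineFrac fraction of the earliest time points used to
#'   estimate the pre-onset noise (default 0.2).
#' @return character: "none", "single" or "multiple".
#' @export
classifyBursts <- function(values, relThreshold = 0.5, noiseMult = 3,
                           baselineFrac = 0.2) {
  n <- length(values)
  nb <- max(3L, ceiling(baselineFrac * n))
  base <- values[seq_len(min(nb, n))]
  floor <- stats::median(base) + noiseMult * max(stats::mad(base),
                                                 1e-12)
  if (max(values) <= floor) return("none")
  above <- values > relThreshold * max(values)
  r <- rle(above)
  epochs <- sum(r$values)
  if (epochs == 1L) "single" else "multiple"
}

#' Post-synchronize single-burst trajectories to their peak
#'
#' Shifts the time axis of every trajectory so its intensity maximum sits
#' at time 0, collects the shifted trajectories on a common relative time
#' grid, and averages them (ignoring missing values at the grid edges).
#'
#' @param trajs list of data.frames with columns time and value (uniform,
#'   identical time step); at least one.
#' @return list with \code{times} (relative, min or s as input),
#'   \code{matrix} (cells x relative times, NA-padded), and \code{mean}.
#' @export
alignToPeak <- function(trajs) {
  stopifnot(length(trajs) >= 1L)
  dt <- diff(trajs[[1]]$time[1:2])
  peaks <- vapply(trajs, function(tr) tr$time[which.max(tr$value)],
                  numeric(1))
  rel <- lapply(seq_along(trajs), function(i) trajs[[i]]$time - peaks[i])
  lo <- min(vapply(rel, min, numeric(1)))
  hi <- max(vapply(rel, max, numeric(1)))
  grid <- seq(lo, hi, by = dt)
  mat <- matrix(NA_real_, length(trajs), length(grid))
  for (i in seq_along(trajs)) {
    idx <- round((rel[[i]] - lo) / dt) + 1L
    mat[i, idx] <- trajs[[i]]$value
  }
  list(times = grid, matrix = mat,
       mean = colMeans(mat, na.rm = TRUE))
}

#' Segment a mean trajectory into three phases
#'
#' Phase I (basal): before the intensity first exceeds \code{riseFrac}
#' times the maximum; phase II (production): from that crossing up to and
#' including the peak; phase III (decline): after the peak. A trace whose
#' peak is at the final point has an empty phase III and is flagged.
#'
#' @param times,values the (mean) trajectory.
#' @param riseFrac rise threshold as a fraction of the maximum
#'   (default 0.2).
#' @return list with integer index vectors \code{phaseI}, \code{phaseII},
#'   \code{phaseIII}, the boundary times \code{tRise} and \code{tPeak}, and
#'   \code{flagged}.
#' @export
phaseSegments <- function(times, values, riseFrac = 0.2) {
  n <- length(values)
  stopifnot(length(times) == n, n >= 2L)
  top <- max(values)
  if (top <= 0)
    return(list(phaseI = integer(0), phaseII = integer(0),
                phaseIII = integer(0), tRise = NA_real_, tPeak = NA_real_,
                flagged = TRUE))
  iPeak <- which.max(values)
  iRise <- which(values > riseFrac * top)[1]
  phaseI <- seq_len(max(iRise - 1L, 0L))
  phaseII <- iRise:iPeak
  phaseIII <- if (iPeak < n) (iPeak + 1L):n else integer(0)
  list(phaseI = phaseI, phaseII = phaseII, phaseIII = phaseIII,
       tRise = times[iRise], tPeak = times[iPeak],
       flagged = length(phaseIII) == 0L)
}

#' Per-phase correlation analysis of a post-synchronized series
#'
#' Computes the short-axis autocorrelation of the (peak-filtered) frames
#' belonging to each phase of a time-lapse stack and averages within each
#' phase, revealing how protein location changes across the expression
#' phases (membrane cross-peaks during production, a broadened origin peak
#' after release).
#'
#' Because the raw correlation scales with the squared intensity, the
#' brightest frames would otherwise dominate a phase average; each frame's
#' function is therefore normalized to unit zero-lag before averaging, so
#' the phase average reflects the typical correlation shape of the phase.
#'
#' @param stack an \code{\link{ImageStack}} of the (cropped, vertically
#'   oriented) time-lapse series, already peak-filtered.
#' @param phases list of index vectors as from \code{\link{phaseSegments}}.
#' @param maxLag,binHeight as in \code{\link{rowAutocorrelation}}.
#' @return named list of \code{\link{CorrelationFunction}} (NULL for an
#'   empty phase).
#' @export
phaseCorrelation <- function(stack, phases, maxLag = 1, binHeight = 20) {
  a <- frames(stack)
  ps <- pixelSize(stack)
  lapply(phases[c("phaseI", "phaseII", "phaseIII")], function(idx) {
    if (length(idx) == 0L) return(NULL)
    acc <- NULL; n <- 0L
    for (t in idx) {
      cf <- rowAutocorrelation(a[, , t], maxLag = maxLag,
                               binHeight = binHeight, pixelSize = ps)
      v <- values(cf)
      v0 <- v[which.min(abs(lags(cf)))]
      if (v0 <= 0) next
      acc <- if (is.null(acc)) v / v0 else acc + v / v0
      n <- n + 1L
      lagAxis <- lags(cf)
    }
    if (n == 0L) return(NULL)
    CorrelationFunction(lagAxis, acc / n, type = "auto")
  })
}
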