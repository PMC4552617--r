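# Bleach-decay quantification: per-cell trajectories, reference correction,
# exponential fits, molecule counts, volumes and concentrations.

#' Per-cell bleaching trajectory
#'
#' Mean fluorescence per pixel within the cell mask, for every frame of a
#' movie.
#'
#' @param movie an \code{\link{ImageStack}} or 3D array.
#' @param mask logical matrix; must contain at least one pixel.
#' @param frameInterval seconds per frame (taken from an ImageStack input).
#' @return data.frame with columns \code{time} (s) and \code{value}
#'   (counts/px).
#' @export
cellTrajectory <- function(movie, mask, frameInterval = NULL) {
  if (is.null(frameInterval))
    frameInterval <- if (is(movie, "ImageStack")) movie@frameInterval else
      0.034
  a <- if (is(movie, "ImageStack")) frames(movie) else movie
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  if (!any(mask)) stop("mask is empty")
  idx <- which(mask)
  nT <- dim(a)[3L]
  v <- vapply(seq_len(nT), function(t) mean(a[, , t][idx]), numeric(1))
  data.frame(time = (seq_len(nT) - 1) * frameInterval, value = v)
}

# Evaluate an ExpDecayFit at given times; infinite tau degenerates to A + c.
evalDecay <- function(fit, times) {
  if (!is.finite(fit@tau)) return(rep(fit@amplitude + fit@offset,
                                      length(times)))
  fit@amplitude * exp(-times / fit@tau) + fit@offset
}

#' Remove reference decays from a trajectory
#'
#' Subtracts the fitted autofluorescence decay (from unlabeled cells) and
#' the fitted background decay (from cell-free regions of the same field of
#' view), evaluated at the trajectory's times, leaving the label-only
#' signal. Pass NULL to skip either correction.
#'
#' @param traj trajectory data.frame (\code{\link{cellTrajectory}}).
#' @param autofluorFit,backgroundFit \code{\link{ExpDecayFit}} reference
#'   fits, or NULL.
#' @return the corrected trajectory data.frame.
#' @export
correctTrajectory <- function(traj, autofluorFit = NULL,
                              backgroundFit = NULL) {
  v <- traj$value
  if (!is.null(autofluorFit)) v <- v - evalDecay(autofluorFit, traj$time)
  if (!is.null(backgroundFit)) v <- v - evalDecay(backgroundFit, traj$time)
  data.frame(time = traj$time, value = v)
}

#' Fit a single-exponential photobleaching decay
#'
#' Unweighted least-squares fit of \code{A exp(-t / tau) + c} by
#' Levenberg-Marquardt. The amplitude A measures the initial label
#' fluorescence; using the fit rather than the first frames pools all
#' frames of the movie and suppresses noise. The fit is flagged when it
#' fails to converge or the decay is unidentifiable (amplitude not
#' significantly above zero, e.g. a flat trace); a flagged fit degenerates
#' to A = 0, c = mean(trace) so it can still serve as a reference.
#'
#' @param traj trajectory data.frame with columns time (s) and value; at
#'   least 10 points.
#' @return an \code{\link{ExpDecayFit}}.
#' @export
fitDecay <- function(traj) {
  stopifnot(nrow(traj) >= 10L)
  t <- traj$time; v <- traj$value
  span <- max(t) - min(t)
  cGuess <- mean(utils::tail(v, max(5L, length(v) %/% 10L)))
  aGuess <- max(v[1] - cGuess, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ A * exp(-t / tau) + c,
                      start = list(A = aGuess, tau = span / 5, c = cGuess),
                      lower = c(A = 0, tau = span * 1e-4, c = -Inf),
                      upper = c(A = Inf, tau = span * 1e3, c = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(ExpDecayFit(amplitude = 0, tau = Inf, offset = mean(v),
                       residualNorm = sum((v - mean(v))^2), flagged = TRUE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  names(se) <- names(cf)
  flagged <- !is.finite(se[["A"]]) || cf[["A"]] < 3 * se[["A"]] ||
    cf[["tau"]] >= span * 1e3 * 0.99
  if (flagged)
    return(ExpDecayFit(amplitude = 0, tau = Inf, offset = mean(v),
                       residualNorm = sum(stats::resid(fit)^2),
                       flagged = TRUE))
  ExpDecayFit(amplitude = cf[["A"]], tau = cf[["tau"]], offset = cf[["c"]],
              residualNorm = sum(stats::resid(fit)^2), flagged = FALSE)
}

#' Molecules per cell from a bleach-fit amplitude
#'
#' The total initial fluorescence of the cell is the fitted mean-per-pixel
#' amplitude times the mask area in pixels; dividing by the single-molecule
#' unit intensity gives the (real-valued) molecule count.
#'
#' @param fit an unflagged \code{\link{ExpDecayFit}} of the corrected cell
#'   trajectory (or a bare amplitude).
#' @param areaPx mask area in pixels.
#' @param calibration an \code{\link{SMCalibration}}.
#' @return molecule count (numeric).
#' @export
countMolecules <- function(fit, areaPx, calibration) {
  if (is.null(calibration) || is.na(calibration@unitIntensity))
    stop("a single-molecule calibration is required")
  A <- if (is(fit, "ExpDecayFit")) fit@amplitude else as.numeric(fit)
  A * areaPx / calibration@unitIntensity
}

#' Cell volume from its mask
#'
#' Fits a spherocylinder to a single-cell mask: the length L is the extent
#' of the mask pixels along the principal axis and the width w solves the
#' footprint-area identity \code{area = w (L - w) + pi w^2 / 4}, which is
#' more robust to pixelation than the transverse extent. Returns the
#' spherocylinder volume in fL.
#'
#' @param mask logical matrix of one cell.
#' @param pixelSize um per pixel.
#' @return list with \code{volume} (fL), \code{length}, \code{width} (um)
#'   and \code{areaPx}.
#' @export
cellVolume <- function(mask, pixelSize) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  xy <- cbind(idx[, 2], idx[, 1]) * pixelSize
  pc <- stats::prcomp(xy)
  major <- pc$x[, 1]
  minorExtent <- diff(range(pc$x[, 2])) / pixelSize
  if (minorExtent < 2) stop("mask thinner than 3 px; cannot fit a cell")
  L <- diff(range(major)) + pixelSize
  area <- nrow(idx) * pixelSize^2
  k <- 1 - pi / 4
  disc <- L^2 - 4 * k * area
  w <- if (disc <= 0) L else (L - sqrt(disc)) / (2 * k)
  w <- min(w, L)
  list(volume = spherocylinderVolume(L, w), length = L, width = w,
       areaPx = nrow(idx))
}

#' Concentration from molecule count and cell volume
#'
#' \code{concentration [nM] = count / (0.6022 * volume [fL])}, the Avogadro
#' identity (1 molecule in 1.6606 fL is 1 nM).
#'
#' @param count molecules per cell.
#' @param volumeFl cell volume (fL, > 0).
#' @return concentration in nM.
#' @export
concentrationNM <- function(count, volumeFl) {
  stopifnot(all(volumeFl > 0))
  count / (0.6022 * volumeFl)
}
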