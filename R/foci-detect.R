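# Focus detection and sub-pixel 2D Gaussian fitting.

#' Default detection threshold for a filtered image
#'
#' mean + nSd standard deviations of the peak-filtered image.
#'
#' @param filtered a peak-filtered image matrix.
#' @param nSd number of standard deviations (default 6).
#' @return a scalar threshold in counts.
#' @export
detectionThreshold <- function(filtered, nSd = 6) {
  mean(filtered) + nSd * stats::sd(filtered)
}

#' Detect candidate foci in a peak-filtered image
#'
#' Local maxima above a threshold, with a minimum mutual separation
#' (stronger candidates suppress weaker ones within \code{minSep} pixels).
#'
#' @param filtered a peak-filtered image matrix
#'   (\code{\link{discoidalFilter}}).
#' @param threshold intensity threshold (counts); default
#'   \code{\link{detectionThreshold}}.
#' @param minSep minimum separation between candidates (px, default 3).
#' @return data.frame with columns \code{row}, \code{col} (1-based pixel
#'   indices), \code{x}, \code{y} (0-based pixel coordinates of the pixel
#'   center, i.e. col - 1 and row - 1) and \code{value}.
#' @export
detectFoci <- function(filtered, threshold = detectionThreshold(filtered),
                       minSep = 3) {
  nr <- nrow(filtered); nc <- ncol(filtered)
  if (nr < 3L || nc < 3L || !is.finite(threshold))
    return(data.frame(row = integer(0), col = integer(0), x = numeric(0),
                      y = numeric(0), value = numeric(0)))
  ctr <- filtered[2:(nr - 1), 2:(nc - 1)]
  isMax <- ctr > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- filtered[2:(nr - 1) + di, 2:(nc - 1) + dj]
    isMax <- isMax & (ctr >= nb)
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(row = integer(0), col = integer(0), x = numeric(0),
                      y = numeric(0), value = numeric(0)))
  rows <- idx[, 1] + 1L; cols <- idx[, 2] + 1L
  vals <- filtered[cbind(rows, cols)]
  ord <- order(-vals)
  rows <- rows[ord]; cols <- cols[ord]; vals <- vals[ord]
  keep <- logical(length(rows))
  for (i in seq_along(rows)) {
    if (any(keep & abs(rows - rows[i]) < minSep &
            abs(cols - cols[i]) < minSep)) next
    keep[i] <- TRUE
  }
  data.frame(row = rows[keep], col = cols[keep],
             x = cols[keep] - 1, y = rows[keep] - 1, value = vals[keep])
}

#' Fit one focus with an elliptical 2D Gaussian
#'
#' Nonlinear least-squares (Levenberg-Marquardt) fit of
#' \code{b + A exp(-(x - x0)^2 / 2 sx^2 - (y - y0)^2 / 2 sy^2)} to a square
#' window of the raw image around a detected candidate. The center
#' uncertainties \code{sigma_x}, \code{sigma_y} are the standard errors of
#' x0 and y0 from the fit covariance and are later used as rendering widths
#' in super-resolution reconstructions. A focus is discarded (NULL) when
#' the fit does not converge, the center escapes the window, the fitted
#' widths leave \code{[0.5, 3] * psfSigma}, or the amplitude is not
#' significant (A < 2 SE(A), e.g. a candidate on flat background).
#'
#' @param raw the raw (unfiltered) image matrix.
#' @param row,col 1-based pixel indices of the candidate.
#' @param window odd window size in px (default 9); the window must lie
#'   inside the image.
#' @param pixelSize um per pixel.
#' @param psfSigma nominal PSF sigma (um) used for width bounds and starting
#'   values.
#' @param frame frame index stored with the focus.
#' @param emGain,readNoise optional camera parameters; when \code{emGain}
#'   is given the fit is weighted by the inverse EMCCD pixel variance so
#'   that the reported center uncertainties are realistic under the
#'   excess-noise model (unweighted least squares otherwise).
#' @return one-row data.frame (x, y in um; amplitude, background in counts;
#'   width_x, width_y, sigma_x, sigma_y in um; integrated_volume in counts;
#'   frame), or NULL when discarded.
#' @export
fitGaussianFocus <- function(raw, row, col, window = 9, pixelSize = 0.1,
                             psfSigma = 0.10, frame = NA_integer_,
                             emGain = NULL, readNoise = 0) {
  hw <- window %/% 2
  if (row - hw < 1 || row + hw > nrow(raw) ||
      col - hw < 1 || col + hw > ncol(raw)) return(NULL)
  sub <- raw[(row - hw):(row + hw), (col - hw):(col + hw)]
  # local coordinates in pixels, candidate pixel center at (hw, hw)
  xs <- rep(0:(window - 1), each = window)
  ys <- rep(0:(window - 1), times = window)
  z <- as.vector(sub)   # column-major: y (row) varies fastest
  sp <- psfSigma / pixelSize
  start <- list(b = min(z), A = max(z) - min(z), x0 = hw, y0 = hw,
                sx = sp, sy = sp)
  # with the EMCCD gain known, weight by the inverse pixel variance
  # (excess-noise model: var ~ 2 g (counts - floor) + read^2), so the fit
  # covariance reports a realistic localization uncertainty
  w <- if (is.null(emGain)) rep(1, length(z)) else
    1 / (2 * emGain * pmax(z - min(z), 0) + readNoise^2 + emGain^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((xs - x0)^2 / (2 * sx^2) +
                        (ys - y0)^2 / (2 * sy^2))),
      start = start, weights = w,
      lower = c(b = -Inf, A = 0, x0 = 0, y0 = 0,
                sx = 0.5 * sp, sy = 0.5 * sp),
      upper = c(b = Inf, A = Inf, x0 = window - 1, y0 = window - 1,
                sx = 3 * sp, sy = 3 * sp),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 6))
  names(se) <- names(cf)
  eps <- 1e-3
  if (cf["A"] <= 0 || !is.finite(se["A"]) || cf["A"] < 2 * se["A"])
    return(NULL)
  if (cf["x0"] <= eps || cf["x0"] >= window - 1 - eps ||
      cf["y0"] <= eps || cf["y0"] >= window - 1 - eps) return(NULL)
  if (cf["sx"] <= 0.5 * sp + eps || cf["sx"] >= 3 * sp - eps ||
      cf["sy"] <= 0.5 * sp + eps || cf["sy"] >= 3 * sp - eps) return(NULL)
  if (!is.finite(se["x0"]) || !is.finite(se["y0"])) return(NULL)
  # window-local px -> image um; pixel centers sit at (index + 0.5) * ps
  xUm <- (col - 1 - hw + cf[["x0"]] + 0.5) * pixelSize
  yUm <- (row - 1 - hw + cf[["y0"]] + 0.5) * pixelSize
  data.frame(
    x = xUm, y = yUm,
    amplitude = cf[["A"]], background = cf[["b"]],
    width_x = cf[["sx"]] * pixelSize, width_y = cf[["sy"]] * pixelSize,
    sigma_x = max(se[["x0"]], 1e-4) * pixelSize,
    sigma_y = max(se[["y0"]], 1e-4) * pixelSize,
    integrated_volume = 2 * pi * cf[["A"]] * cf[["sx"]] * cf[["sy"]],
    frame = frame)
}

#' Detect and fit all foci in a movie
#'
#' Applies the discoidal filter per frame, detects candidates and fits each
#' on the raw frame, collecting the surviving foci of all frames.
#'
#' @param stack an \code{\link{ImageStack}} (raw movie).
#' @param psfSigma nominal PSF sigma (um).
#' @param threshold detection threshold; default per frame from
#'   \code{\link{detectionThreshold}}.
#' @param rInner,rOuter discoidal filter radii (px).
#' @param window fit window (px).
#' @param frames frame indices to analyze (default all).
#' @param minIsolation if > 0, candidates with another candidate closer
#'   than this many pixels (same frame) are dropped before fitting, so
#'   overlapping spots do not bias amplitudes.
#' @return a data.frame of foci (possibly 0 rows).
#' @export
fitFociStack <- function(stack, psfSigma = 0.10, threshold = NULL,
                         rInner = 2, rOuter = 5, window = 9,
                         frames = seq_len(nFrames(stack)),
                         minIsolation = 0) {
  a <- frames(stack)
  ps <- pixelSize(stack)
  out <- vector("list", length(frames))
  for (ii in seq_along(frames)) {
    t <- frames[ii]
    filt <- discoidalFilter(a[, , t], rInner, rOuter)
    thr <- if (is.null(threshold)) detectionThreshold(filt) else threshold
    cand <- detectFoci(filt, thr)
    if (nrow(cand) == 0L) next
    if (minIsolation > 0 && nrow(cand) > 1L) {
      d <- as.matrix(stats::dist(cand[, c("row", "col")]))
      diag(d) <- Inf
      cand <- cand[apply(d, 1, min) >= minIsolation, , drop = FALSE]
      if (nrow(cand) == 0L) next
    }
    rows <- lapply(seq_len(nrow(cand)), function(i)
      fitGaussianFocus(a[, , t], cand$row[i], cand$col[i], window, ps,
                       psfSigma, frame = t))
    out[[ii]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                      background = numeric(0), width_x = numeric(0),
                      width_y = numeric(0), sigma_x = numeric(0),
                      sigma_y = numeric(0), integrated_volume = numeric(0),
                      frame = integer(0))
  res
}
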