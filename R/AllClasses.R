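#' @import methods
NULL

#' Spherocylinder model of one rod-shaped cell
#'
#' Geometry of a single bacterium modeled as a spherocylinder: a cylinder of
#' diameter \code{width} capped by two hemispheres, with pole-to-pole extent
#' \code{length}. The projected footprint on the image plane is a rectangle
#' of size \code{(length - width) x width} capped by two semicircles of
#' radius \code{width/2}.
#'
#' @slot center numeric(2), position of the cell centroid in the image frame
#'   (micrometers; x = column, y = row).
#' @slot orientation numeric(1), angle (radians) of the long axis measured
#'   from the image vertical.
#' @slot length numeric(1), pole-to-pole extent L (micrometers).
#' @slot width numeric(1), cell diameter w (micrometers); L >= w > 0.
#' @exportClass CellGeometry
setClass("CellGeometry",
  representation(center = "numeric", orientation = "numeric",
                 length = "numeric", width = "numeric"),
  prototype(center = c(0, 0), orientation = 0, length = 3, width = 0.6))

setValidity("CellGeometry", function(object) {
  msg <- NULL
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    msg <- c(msg, "'center' must be a finite numeric of length 2")
  if (length(object@width) != 1L || object@width <= 0)
    msg <- c(msg, "'width' must be a single positive number")
  if (length(object@length) != 1L || object@length < object@width)
    msg <- c(msg, "'length' must be a single number >= 'width'")
  if (is.null(msg)) TRUE else msg
})

#' @rdname CellGeometry-class
#' @param center,orientation,length,width see slot documentation.
#' @return a \code{CellGeometry} object.
#' @export
CellGeometry <- function(center = c(0, 0), orientation = 0,
                         length = 3, width = 0.6) {
  new("CellGeometry", center = as.numeric(center),
      orientation = as.numeric(orientation),
      length = as.numeric(length), width = as.numeric(width))
}

#' Photophysical rate parameters of the fluorophore
#'
#' Under constant illumination a bright fluorophore photobleaches with mean
#' bright lifetime \code{bleachTau} (so the expected bright survival without
#' blinking is exp(-t/bleachTau)), may shelve into a reversible dark state at
#' rate \code{darkRate}, and dark molecules return to the bright state at
#' rate \code{returnRate}. Bleaching is absorbing and occurs from the bright
#' state only (dark molecules are photoprotected). \code{photonRate} is the
#' expected number of detected photons per bright emitter per second.
#'
#' @slot bleachTau numeric(1), mean bright lifetime (s); \code{Inf} disables
#'   bleaching.
#' @slot darkRate numeric(1), bright-to-dark rate (1/s).
#' @slot returnRate numeric(1), dark-to-bright rate (1/s).
#' @slot photonRate numeric(1), photons per bright emitter per second.
#' @exportClass Photophysics
setClass("Photophysics",
  representation(bleachTau = "numeric", darkRate = "numeric",
                 returnRate = "numeric", photonRate = "numeric"),
  prototype(bleachTau = 5, darkRate = 0, returnRate = 0, photonRate = 5000))

setValidity("Photophysics", function(object) {
  v <- c(object@bleachTau, object@darkRate, object@returnRate,
         object@photonRate)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0))
    "all rates must be single non-negative numbers" else TRUE
})

#' @rdname Photophysics-class
#' @param bleachTau,darkRate,returnRate,photonRate see slot documentation.
#' @return a \code{Photophysics} object.
#' @export
Photophysics <- function(bleachTau = 5, darkRate = 0, returnRate = 0,
                         photonRate = 5000) {
  new("Photophysics", bleachTau = bleachTau, darkRate = darkRate,
      returnRate = returnRate, photonRate = photonRate)
}

#' Camera and acquisition settings
#'
#' Describes the pixel grid, point-spread function, frame timing and the
#' EMCCD noise model used when rendering synthetic frames. The noise model
#' is the standard EMCCD approximation: detected photons are Poisson, the
#' electron-multiplied output is Gamma(shape = photons, scale = emGain),
#' Gaussian read noise and a constant camera offset are added, and the
#' result is clamped at zero and digitized.
#'
#' @slot dim integer(2), image size in pixels (rows, columns).
#' @slot pixelSize numeric(1), micrometers per pixel.
#' @slot psfSigma numeric(1), in-focus Gaussian PSF standard deviation
#'   (micrometers).
#' @slot depthOfField numeric(1), axial scale (micrometers) of defocus: an
#'   emitter at out-of-plane distance z renders with sigma(z) = psfSigma *
#'   sqrt(1 + (z / depthOfField)^2) (Gaussian-beam model, focal plane at
#'   the cell midplane); 0 or Inf disables defocus.
#' @slot frameInterval numeric(1), seconds per frame.
#' @slot nFrames integer(1), number of frames per movie.
#' @slot emGain numeric(1), electron-multiplication gain (counts/photon).
#' @slot readNoise numeric(1), RMS read noise (counts).
#' @slot offset numeric(1), camera baseline offset (counts).
#' @slot backgroundRate numeric(1), coverslip background (photons/px/s),
#'   scaled by the illumination field.
#' @slot autofluorRate numeric(1), cellular autofluorescence (photons/px/s)
#'   added inside cell footprints, scaled by the illumination field.
#' @slot illumination matrix of relative illumination intensity in (0, 1]
#'   on the pixel grid, or a 0 x 0 matrix for flat illumination.
#' @exportClass Acquisition
setClass("Acquisition",
  representation(dim = "integer", pixelSize = "numeric", psfSigma = "numeric",
                 depthOfField = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 emGain = "numeric", readNoise = "numeric", offset = "numeric",
                 backgroundRate = "numeric", autofluorRate = "numeric",
                 illumination = "matrix"),
  prototype(dim = c(128L, 128L), pixelSize = 0.1, psfSigma = 0.10,
            depthOfField = 0.10,
            frameInterval = 0.034, nFrames = 296L, emGain = 30,
            readNoise = 20, offset = 100, backgroundRate = 50,
            autofluorRate = 30, illumination = matrix(numeric(0), 0, 0)))

setValidity("Acquisition", function(object) {
  msg <- NULL
  if (length(object@dim) != 2L || any(object@dim < 1L))
    msg <- c(msg, "'dim' must be two positive integers")
  if (object@pixelSize <= 0 || object@psfSigma <= 0 ||
      object@frameInterval <= 0)
    msg <- c(msg, "pixelSize, psfSigma and frameInterval must be positive")
  if (object@nFrames < 1L) msg <- c(msg, "'nFrames' must be >= 1")
  if (length(object@illumination) > 0) {
    if (!identical(dim(object@illumination), as.integer(object@dim)))
      msg <- c(msg, "'illumination' must match 'dim'")
    else if (any(object@illumination <= 0) || max(object@illumination) > 1 + 1e-9)
      msg <- c(msg, "'illumination' values must lie in (0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname Acquisition-class
#' @param dim,pixelSize,psfSigma,depthOfField,frameInterval,nFrames,emGain,readNoise,offset,backgroundRate,autofluorRate,illumination
#'   see slot documentation.
#' @return an \code{Acquisition} object.
#' @export
Acquisition <- function(dim = c(128L, 128L), pixelSize = 0.1, psfSigma = 0.10,
                        depthOfField = 0.10,
                        frameInterval = 0.034, nFrames = 296L, emGain = 30,
                        readNoise = 20, offset = 100, backgroundRate = 50,
                        autofluorRate = 30,
                        illumination = matrix(numeric(0), 0, 0)) {
  new("Acquisition", dim = as.integer(dim), pixelSize = pixelSize,
      psfSigma = psfSigma, depthOfField = depthOfField,
      frameInterval = frameInterval,
      nFrames = as.integer(nFrames), emGain = emGain, readNoise = readNoise,
      offset = offset, backgroundRate = backgroundRate,
      autofluorRate = autofluorRate, illumination = illumination)
}

#' Three-phase expression program for time-lapse simulations
#'
#' Deterministic molecule-count program emulating an induced burst of
#' protein production: no molecules before \code{tOnset}, linear production
#' at \code{productionRate} between \code{tOnset} and \code{tPeak}, and
#' first-order decay at \code{decayRate} after \code{tPeak}. New molecules
#' are seeded in \code{initialMode}; at \code{tRelease} all molecules switch
#' to \code{releasedMode} (membrane release into the cytosol).
#'
#' @slot tOnset numeric(1), production onset (minutes).
#' @slot productionRate numeric(1), molecules per minute during the burst.
#' @slot tPeak numeric(1), end of production (minutes); tOnset <= tPeak.
#' @slot tRelease numeric(1), mode-switch time (minutes); tPeak <= tRelease.
#' @slot decayRate numeric(1), decay constant after the peak (1/min).
#' @slot initialMode character(1), emitter mode of newly produced molecules.
#' @slot releasedMode character(1), emitter mode after release.
#' @exportClass ExpressionProgram
setClass("ExpressionProgram",
  representation(tOnset = "numeric", productionRate = "numeric",
                 tPeak = "numeric", tRelease = "numeric",
                 decayRate = "numeric", initialMode = "character",
                 releasedMode = "character"),
  prototype(tOnset = 60, productionRate = 0.5, tPeak = 100, tRelease = 100,
            decayRate = 0.05, initialMode = "membrane",
            releasedMode = "cytosolic"))

setValidity("ExpressionProgram", function(object) {
  msg <- NULL
  if (!(object@tOnset <= object@tPeak && object@tPeak <= object@tRelease))
    msg <- c(msg, "need tOnset <= tPeak <= tRelease")
  if (object@productionRate < 0 || object@decayRate < 0)
    msg <- c(msg, "rates must be non-negative")
  ok <- c("membrane", "cytosolic", "static")
  if (!object@initialMode %in% ok || !object@releasedMode %in% ok)
    msg <- c(msg, "modes must be one of 'membrane', 'cytosolic', 'static'")
  if (is.null(msg)) TRUE else msg
})

#' @rdname ExpressionProgram-class
#' @param tOnset,productionRate,tPeak,tRelease,decayRate,initialMode,releasedMode
#'   see slot documentation.
#' @return an \code{ExpressionProgram} object.
#' @export
ExpressionProgram <- function(tOnset = 60, productionRate = 0.5, tPeak = 100,
                              tRelease = 100, decayRate = 0.05,
                              initialMode = "membrane",
                              releasedMode = "cytosolic") {
  new("ExpressionProgram", tOnset = tOnset, productionRate = productionRate,
      tPeak = tPeak, tRelease = tRelease, decayRate = decayRate,
      initialMode = initialMode, releasedMode = releasedMode)
}

#' A movie as an image stack with physical calibration
#'
#' Thin container for a fluorescence movie: a numeric array of dimension
#' rows x columns x frames together with the pixel size and frame interval
#' needed to interpret it physically.
#'
#' @slot frames numeric array, rows x columns x frames (counts).
#' @slot pixelSize numeric(1), micrometers per pixel.
#' @slot frameInterval numeric(1), seconds (time-sampling) or the spacing of
#'   a time-lapse series, in seconds.
#' @exportClass ImageStack
setClass("ImageStack",
  representation(frames = "array", pixelSize = "numeric",
                 frameInterval = "numeric"))

setValidity("ImageStack", function(object) {
  if (length(dim(object@frames)) != 3L)
    return("'frames' must be a 3D array (rows x cols x frames)")
  if (object@pixelSize <= 0 || object@frameInterval <= 0)
    return("pixelSize and frameInterval must be positive")
  TRUE
})

#' @rdname ImageStack-class
#' @param frames a 3D array, or a matrix (promoted to a single frame).
#' @param pixelSize,frameInterval see slot documentation.
#' @return an \code{ImageStack} object.
#' @export
ImageStack <- function(frames, pixelSize = 0.1, frameInterval = 0.034) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  new("ImageStack", frames = frames, pixelSize = pixelSize,
      frameInterval = frameInterval)
}

#' Per-frame ground truth of a simulated movie
#'
#' Bookkeeping of the simulator: per-cell counts of non-bleached molecules
#' per frame, per-frame emitter positions and states in image coordinates,
#' and (for two-channel scenes) the generated colocalized-pair labels.
#'
#' @slot counts numeric matrix, cells x frames, number of non-bleached
#'   molecules assigned to each cell at each frame.
#' @slot positions data.frame with columns frame, cell, id, x, y (um, image
#'   frame), mode, state.
#' @slot pairs data.frame of generated two-channel pairs (may be empty).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(counts = "matrix", positions = "data.frame",
                 pairs = "data.frame"),
  prototype(counts = matrix(numeric(0), 0, 0),
            positions = data.frame(), pairs = data.frame()))

#' A spatial correlation function along the cell short axis
#'
#' Correlation values as a function of the distance lag (micrometers) by
#' which an image is shifted along the horizontal axis against a second
#' image (itself, for autocorrelation).
#'
#' @slot lags numeric, distance lags (um), symmetric about 0.
#' @slot values numeric, correlation per lag.
#' @slot type character(1), "auto" or "cross".
#' @exportClass CorrelationFunction
setClass("CorrelationFunction",
  representation(lags = "numeric", values = "numeric", type = "character"),
  prototype(type = "auto"))

setValidity("CorrelationFunction", function(object) {
  if (length(object@lags) != length(object@values))
    return("'lags' and 'values' must have the same length")
  if (!object@type %in% c("auto", "cross"))
    return("'type' must be 'auto' or 'cross'")
  TRUE
})

#' @rdname CorrelationFunction-class
#' @param lags,values,type see slot documentation.
#' @return a \code{CorrelationFunction} object.
#' @export
CorrelationFunction <- function(lags, values, type = "auto") {
  new("CorrelationFunction", lags = as.numeric(lags),
      values = as.numeric(values), type = type)
}

#' A time course of correlation functions
#'
#' A time x lag matrix of correlation values, optionally normalized so that
#' after dividing each time point by its mean cellular intensity the maximal
#' zero-lag value over the whole course equals 1.
#'
#' @slot times numeric, time of each row (minutes).
#' @slot lags numeric, distance lags (um).
#' @slot values numeric matrix, times x lags.
#' @slot normalization character(1), "zero-lag-max-one" or "none".
#' @exportClass CorrelationTimecourse
setClass("CorrelationTimecourse",
  representation(times = "numeric", lags = "numeric", values = "matrix",
                 normalization = "character"),
  prototype(normalization = "none"))

setValidity("CorrelationTimecourse", function(object) {
  if (nrow(object@values) != length(object@times) ||
      ncol(object@values) != length(object@lags))
    return("'values' must be times x lags")
  if (!object@normalization %in% c("zero-lag-max-one", "none"))
    return("unknown normalization tag")
  if (object@normalization == "zero-lag-max-one" &&
      length(object@values) > 0) {
    i0 <- which.min(abs(object@lags))
    if (abs(max(object@values) - 1) > 1e-6)
      return("normalized time course must have maximum 1")
    if (abs(max(object@values[, i0]) - 1) > 1e-6)
      return("normalized maximum must occur at zero lag")
  }
  TRUE
})

#' Single-exponential photobleaching decay fit
#'
#' Parameters of the model A * exp(-t / tau) + c fitted to a bleaching
#' trajectory by nonlinear least squares; the amplitude A measures the
#' initial label fluorescence.
#'
#' @slot amplitude numeric(1), A (counts).
#' @slot tau numeric(1), decay time constant (s).
#' @slot offset numeric(1), c (counts).
#' @slot residualNorm numeric(1), residual sum of squares.
#' @slot flagged logical(1), TRUE when the fit did not converge or the decay
#'   is not identifiable (e.g. a flat trace).
#' @exportClass ExpDecayFit
setClass("ExpDecayFit",
  representation(amplitude = "numeric", tau = "numeric", offset = "numeric",
                 residualNorm = "numeric", flagged = "logical"),
  prototype(amplitude = 0, tau = Inf, offset = 0, residualNorm = 0,
            flagged = FALSE))

#' @rdname ExpDecayFit-class
#' @param amplitude,tau,offset,residualNorm,flagged see slot documentation.
#' @return an \code{ExpDecayFit} object.
#' @export
ExpDecayFit <- function(amplitude = 0, tau = Inf, offset = 0,
                        residualNorm = 0, flagged = FALSE) {
  new("ExpDecayFit", amplitude = amplitude, tau = tau, offset = offset,
      residualNorm = residualNorm, flagged = flagged)
}

#' Single-molecule intensity calibration
#'
#' The mean integrated fluorescence signal of one molecule in one frame
#' (counts), measured either from dark-state returns late in a movie
#' ("returns") or from change-point photobleaching step sizes ("steps").
#'
#' @slot unitIntensity numeric(1), counts per molecule per frame.
#' @slot source character(1), "returns" or "steps".
#' @slot nObservations integer(1), number of single-molecule observations.
#' @slot flagged logical(1), TRUE when based on fewer than 10 observations.
#' @exportClass SMCalibration
setClass("SMCalibration",
  representation(unitIntensity = "numeric", source = "character",
                 nObservations = "integer", flagged = "logical"),
  prototype(unitIntensity = NA_real_, source = "returns",
            nObservations = 0L, flagged = TRUE))

setValidity("SMCalibration", function(object) {
  if (!object@source %in% c("returns", "steps"))
    return("'source' must be 'returns' or 'steps'")
  if (!is.na(object@unitIntensity) && object@unitIntensity <= 0)
    return("'unitIntensity' must be positive")
  TRUE
})

#' @rdname SMCalibration-class
#' @param unitIntensity,source,nObservations,flagged see slot documentation.
#' @return an \code{SMCalibration} object.
#' @export
SMCalibration <- function(unitIntensity, source = "returns",
                          nObservations = 0L,
                          flagged = nObservations < 10L) {
  new("SMCalibration", unitIntensity = unitIntensity, source = source,
      nObservations = as.integer(nObservations), flagged = flagged)
}
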