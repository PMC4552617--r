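# Accessor generics and show methods for the S4 containers.

#' @name memloc-accessors
#' @title Accessors for memloc S4 containers
#' @description Small accessor generics for the package's data containers.
#' @param object an S4 object from this package.
#' @return the slot value.
NULL

#' @rdname memloc-accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname memloc-accessors
#' @export
setMethod("frames", "ImageStack", function(object) object@frames)

#' @rdname memloc-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname memloc-accessors
#' @export
setMethod("pixelSize", "ImageStack", function(object) object@pixelSize)
#' @rdname memloc-accessors
#' @export
setMethod("pixelSize", "Acquisition", function(object) object@pixelSize)

#' @rdname memloc-accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname memloc-accessors
#' @export
setMethod("frameInterval", "ImageStack", function(object) object@frameInterval)
#' @rdname memloc-accessors
#' @export
setMethod("frameInterval", "Acquisition", function(object) object@frameInterval)

#' @rdname memloc-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname memloc-accessors
#' @export
setMethod("nFrames", "ImageStack", function(object) dim(object@frames)[3L])

#' @rdname memloc-accessors
#' @export
setGeneric("lags", function(object) standardGeneric("lags"))
#' @rdname memloc-accessors
#' @export
setMethod("lags", "CorrelationFunction", function(object) object@lags)
#' @rdname memloc-accessors
#' @export
setMethod("lags", "CorrelationTimecourse", function(object) object@lags)

#' @rdname memloc-accessors
#' @export
setGeneric("values", function(object) standardGeneric("values"))
#' @rdname memloc-accessors
#' @export
setMethod("values", "CorrelationFunction", function(object) object@values)
#' @rdname memloc-accessors
#' @export
setMethod("values", "CorrelationTimecourse", function(object) object@values)

#' @rdname memloc-accessors
#' @export
setGeneric("unitIntensity", function(object) standardGeneric("unitIntensity"))
#' @rdname memloc-accessors
#' @export
setMethod("unitIntensity", "SMCalibration",
          function(object) object@unitIntensity)

#' @rdname memloc-accessors
#' @export
setGeneric("amplitude", function(object) standardGeneric("amplitude"))
#' @rdname memloc-accessors
#' @export
setMethod("amplitude", "ExpDecayFit", function(object) object@amplitude)

#' @rdname memloc-accessors
#' @export
setGeneric("decayTau", function(object) standardGeneric("decayTau"))
#' @rdname memloc-accessors
#' @export
setMethod("decayTau", "ExpDecayFit", function(object) object@tau)

#' @rdname memloc-accessors
#' @export
setGeneric("isFlagged", function(object) standardGeneric("isFlagged"))
#' @rdname memloc-accessors
#' @export
setMethod("isFlagged", "ExpDecayFit", function(object) object@flagged)
#' @rdname memloc-accessors
#' @export
setMethod("isFlagged", "SMCalibration", function(object) object@flagged)

#' @rdname memloc-accessors
#' @export
setGeneric("truthCounts", function(object) standardGeneric("truthCounts"))
#' @rdname memloc-accessors
#' @export
setMethod("truthCounts", "GroundTruth", function(object) object@counts)

#' @rdname memloc-accessors
#' @export
setGeneric("truthPositions", function(object) standardGeneric("truthPositions"))
#' @rdname memloc-accessors
#' @export
setMethod("truthPositions", "GroundTruth", function(object) object@positions)

#' @rdname memloc-accessors
#' @export
setGeneric("truthPairs", function(object) standardGeneric("truthPairs"))
#' @rdname memloc-accessors
#' @export
setMethod("truthPairs", "GroundTruth", function(object) object@pairs)

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf(
    "CellGeometry: L = %.2f um, w = %.2f um, center = (%.2f, %.2f) um, %.1f deg from vertical\n",
    object@length, object@width, object@center[1], object@center[2],
    object@orientation * 180 / pi))
})

setMethod("show", "Photophysics", function(object) {
  cat(sprintf(
    "Photophysics: bleachTau = %.3g s, darkRate = %.3g /s, returnRate = %.3g /s, photonRate = %.3g /s\n",
    object@bleachTau, object@darkRate, object@returnRate, object@photonRate))
})

setMethod("show", "Acquisition", function(object) {
  cat(sprintf(
    "Acquisition: %d x %d px (%.3g um/px), %d frames x %.3g s, PSF sigma %.3g um\n",
    object@dim[1], object@dim[2], object@pixelSize, object@nFrames,
    object@frameInterval, object@psfSigma))
  cat(sprintf("  EM gain %.3g, read noise %.3g, offset %.3g, background %.3g ph/px/s, autofluorescence %.3g ph/px/s, %s illumination\n",
    object@emGain, object@readNoise, object@offset, object@backgroundRate,
    object@autofluorRate,
    if (length(object@illumination)) "shaped" else "flat"))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack: %d x %d px, %d frame(s), %.3g um/px, %.3g s/frame\n",
              d[1], d[2], d[3], object@pixelSize, object@frameInterval))
})

setMethod("show", "CorrelationFunction", function(object) {
  cat(sprintf("CorrelationFunction (%s): %d lags in [%.2f, %.2f] um\n",
              object@type, length(object@lags), min(object@lags),
              max(object@lags)))
})

setMethod("show", "CorrelationTimecourse", function(object) {
  cat(sprintf(
    "CorrelationTimecourse: %d time points x %d lags, normalization '%s'\n",
    length(object@times), length(object@lags), object@normalization))
})

setMethod("show", "ExpDecayFit", function(object) {
  cat(sprintf("ExpDecayFit: A = %.4g, tau = %.4g s, c = %.4g%s\n",
              object@amplitude, object@tau, object@offset,
              if (object@flagged) " [flagged]" else ""))
})

setMethod("show", "SMCalibration", function(object) {
  cat(sprintf("SMCalibration (%s): %.4g counts/molecule from %d observations%s\n",
              object@source, object@unitIntensity, object@nObservations,
              if (object@flagged) " [low confidence]" else ""))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cell(s) x %d frame(s), %d position records\n",
              nrow(object@counts), ncol(object@counts),
              nrow(object@positions)))
})

setMethod("show", "ExpressionProgram", function(object) {
  cat(sprintf(
    "ExpressionProgram: onset %g min, %g molecules/min to peak %g min, release %g min, decay %g /min (%s -> %s)\n",
    object@tOnset, object@productionRate, object@tPeak, object@tRelease,
    object@decayRate, object@initialMode, object@releasedMode))
})
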