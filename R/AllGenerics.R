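#' @describeIn CalibratedRecording-class sample vector accessor
#' @param object a `CalibratedRecording` or `CalibrationTone`
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @describeIn CalibratedRecording-class sampling rate accessor (Hz)
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @describeIn CalibratedRecording-class source distance accessor (cm)
#' @export
setGeneric("distanceCm", function(object) standardGeneric("distanceCm"))

#' @describeIn CalibratedRecording-class duration in seconds
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @describeIn TrendModel-class trend family accessor
#' @export
setGeneric("trendFamily", function(object) standardGeneric("trendFamily"))

#' @describeIn TrendModel-class named fixed-effect estimates
#' @export
setGeneric("fixedCoefs", function(object) standardGeneric("fixedCoefs"))

#' @describeIn ActiveSpaceEstimate-class estimated range in cm
#' @export
setGeneric("rangeCm", function(object) standardGeneric("rangeCm"))

#' @export
#' @describeIn CalibratedRecording-class accessor methods
setMethod("samples", "CalibratedRecording", function(object) object@samples)

#' @export
#' @describeIn CalibrationTone-class tone sample accessor
setMethod("samples", "CalibrationTone", function(object) object@samples)

#' @export
#' @describeIn CalibratedRecording-class sampling rate
setMethod("sampleRate", "CalibratedRecording",
          function(object) object@sampleRate)

#' @export
#' @describeIn CalibrationTone-class sampling rate
setMethod("sampleRate", "CalibrationTone", function(object) object@sampleRate)

#' @export
#' @describeIn CalibratedRecording-class source distance (cm)
setMethod("distanceCm", "CalibratedRecording",
          function(object) object@distanceCm)

#' @export
#' @describeIn CalibratedRecording-class duration (s)
setMethod("duration", "CalibratedRecording",
          function(object) length(object@samples) / object@sampleRate)

#' @export
#' @describeIn TrendModel-class trend family
setMethod("trendFamily", "TrendModel", function(object) object@family)

#' @export
#' @describeIn TrendModel-class fixed effects
setMethod("fixedCoefs", "TrendModel", function(object) object@fixed)

#' @export
#' @describeIn ActiveSpaceEstimate-class range (cm)
setMethod("rangeCm", "ActiveSpaceEstimate", function(object) object@rangeCm)

setMethod("show", "CalibratedRecording", function(object) {
  cat(sprintf(
    "CalibratedRecording: %d samples @ %g Hz (%.3f s)\n",
    length(object@samples), object@sampleRate,
    length(object@samples) / object@sampleRate
  ))
  cat(sprintf(
    "  species=%s individual=%s array=%s distance=%s cm channel=%d\n",
    object@species, object@individual,
    ifelse(is.na(object@arrayId), "NA", object@arrayId),
    ifelse(is.na(object@distanceCm), "NA", format(object@distanceCm)),
    object@channel
  ))
})

setMethod("show", "CalibrationTone", function(object) {
  cat(sprintf(
    "CalibrationTone: %d samples @ %g Hz, reference %.1f dB SPL RMS\n",
    length(object@samples), object@sampleRate, object@referenceSplDb
  ))
})

setMethod("show", "TrendModel", function(object) {
  cat(sprintf("TrendModel (%s) for '%s'\n", object@family, object@response))
  if (length(object@fixed)) {
    cat("  fixed:",
        paste(sprintf("%s=%.5g", names(object@fixed), object@fixed),
              collapse = ", "), "\n")
  }
  cat(sprintf("  sigma_u=%.4g sigma_e=%.4g logLik=%.2f (n=%d, groups=%d)\n",
              object@sigmaU, object@sigmaE, object@logLik,
              object@nObs, object@nGroups))
})

setMethod("show", "ActiveSpaceEstimate", function(object) {
  cat(sprintf(
    "ActiveSpaceEstimate: range = %s cm at threshold %.1f dB SPL\n",
    format(object@rangeCm), object@thresholdDb
  ))
})
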