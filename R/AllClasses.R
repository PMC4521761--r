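#' CalibratedRecording: a waveform with propagation metadata
#'
#' A mono waveform (dimensionless sample units in \[-1, 1\] for integer PCM
#' sources) together with the metadata needed to place it in a propagation
#' study: emitter-to-microphone distance, individual, species and microphone
#' array. Absolute amplitude is meaningless until a calibration gain from a
#' reference tone maps sample RMS to dB SPL (see [calibrationGain()]).
#'
#' @slot samples numeric vector of samples.
#' @slot sampleRate sampling rate in Hz.
#' @slot distanceCm distance from the sound source, cm.
#' @slot individual individual (subject) identifier.
#' @slot species species label.
#' @slot arrayId microphone array identifier (1 or 2 in the canonical design).
#' @slot channel 0-based channel index the samples came from.
#'
#' @seealso [readWave()], [callSpl()]
#' @export
setClass("CalibratedRecording",
  representation(
    samples    = "numeric",
    sampleRate = "numeric",
    distanceCm = "numeric",
    individual = "character",
    species    = "character",
    arrayId    = "integer",
    channel    = "integer"
  ),
  prototype(
    distanceCm = NA_real_, individual = NA_character_,
    species = NA_character_, arrayId = NA_integer_, channel = 0L
  )
)

setValidity("CalibratedRecording", function(object) {
  msg <- character()
  if (length(object@samples) == 0L) msg <- c(msg, "samples must be nonempty")
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0) {
    msg <- c(msg, "sampleRate must be a single positive number")
  }
  if (!is.na(object@distanceCm) && object@distanceCm <= 0) {
    msg <- c(msg, "distanceCm must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' CalibrationTone: a reference tone of known sound pressure level
#'
#' A recorded calibrator tone whose true level (dB SPL RMS) is known, recorded
#' at the same gain as the study recordings. It anchors the mapping from
#' dimensionless sample units to absolute SPL. The canonical study design uses
#' a 1 kHz tone at 93.8 dB SPL RMS.
#'
#' @slot samples numeric vector of tone samples.
#' @slot sampleRate sampling rate in Hz.
#' @slot referenceSplDb the tone's true level, dB SPL RMS.
#'
#' @seealso [calibrationGain()]
#' @export
setClass("CalibrationTone",
  representation(
    samples        = "numeric",
    sampleRate     = "numeric",
    referenceSplDb = "numeric"
  )
)

setValidity("CalibrationTone", function(object) {
  msg <- character()
  if (length(object@samples) == 0L) msg <- c(msg, "samples must be nonempty")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0) {
    msg <- c(msg, "sampleRate must be a single positive number")
  }
  if (length(object@referenceSplDb) != 1L ||
      !is.finite(object@referenceSplDb)) {
    msg <- c(msg, "referenceSplDb must be a single finite number")
  }
  if (length(msg)) msg else TRUE
})

#' TrendModel: a fitted random-intercept distance trend
#'
#' The result of fitting one of the four trend families to a feature-table
#' response against distance (cm) with a per-individual random intercept:
#' `none` (intercept only), `linear` (`a + b*dist`), `quadratic`
#' (`a + b*dist + c*dist^2`) or `exponential` (`a + b*exp(-c*dist)`).
#'
#' @slot family one of `"none"`, `"linear"`, `"quadratic"`, `"exponential"`.
#' @slot fixed named numeric vector of fixed-effect estimates (`a`, `b`, `c`
#'   as applicable).
#' @slot sigmaU random-intercept standard deviation.
#' @slot sigmaE residual standard deviation.
#' @slot logLik maximised log-likelihood (ML).
#' @slot nObs number of observations.
#' @slot nGroups number of individuals (random-effect groups).
#' @slot response name of the modelled feature column.
#' @slot fit the underlying fitted model object (`lmerMod` or `nlme`).
#'
#' @seealso [selectTrend()], [fitExponentialTrend()], [estimateRange()]
#' @export
setClass("TrendModel",
  representation(
    family   = "character",
    fixed    = "numeric",
    sigmaU   = "numeric",
    sigmaE   = "numeric",
    logLik   = "numeric",
    nObs     = "integer",
    nGroups  = "integer",
    response = "character",
    fit      = "ANY"
  )
)

setValidity("TrendModel", function(object) {
  msg <- character()
  if (!object@family %in% c("none", "linear", "quadratic", "exponential")) {
    msg <- c(msg, "unknown trend family")
  }
  if (length(object@sigmaU) == 1L && is.finite(object@sigmaU) &&
      object@sigmaU < 0) {
    msg <- c(msg, "sigmaU must be >= 0")
  }
  if (length(object@sigmaE) == 1L && is.finite(object@sigmaE) &&
      object@sigmaE <= 0) {
    msg <- c(msg, "sigmaE must be > 0")
  }
  if (object@family == "exponential" &&
      (!("c" %in% names(object@fixed)) || object@fixed[["c"]] <= 0)) {
    msg <- c(msg, "exponential decay rate c must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' ActiveSpaceEstimate: communication range implied by an amplitude trend
#'
#' The distance at which a fitted SPL-versus-distance curve crosses a
#' receiver's detection threshold. Finite only when the threshold lies
#' strictly between the curve's asymptote and its level at the reference
#' distance; `Inf` when the level never falls to threshold, 0 when the signal
#' is already below threshold at the reference distance.
#'
#' @slot rangeCm estimated communication range, cm (possibly 0 or `Inf`).
#' @slot thresholdDb detection threshold, dB SPL.
#' @slot model the [TrendModel-class] the range was derived from.
#'
#' @seealso [estimateRange()]
#' @export
setClass("ActiveSpaceEstimate",
  representation(
    rangeCm     = "numeric",
    thresholdDb = "numeric",
    model       = "TrendModel"
  )
)

setValidity("ActiveSpaceEstimate", function(object) {
  if (length(object@rangeCm) != 1L || is.na(object@rangeCm) ||
      object@rangeCm < 0) {
    "rangeCm must be a single number >= 0 (Inf allowed)"
  } else TRUE
})
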