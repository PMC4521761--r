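.rms <- function(x) sqrt(mean(x^2))

#' Calibration gain from a reference tone
#'
#' Returns the dB offset `G` such that `SPL(x) = G + 20*log10(RMS(x))` for any
#' signal `x` recorded at the same gain as the tone. By construction the tone
#' itself maps back to its known level.
#'
#' @param tone a [CalibrationTone-class].
#' @return the gain `G` in dB.
#' @examples
#' tone <- new("CalibrationTone", samples = rep(0.1, 1000),
#'             sampleRate = 44100, referenceSplDb = 93.8)
#' calibrationGain(tone)  # 113.8
#' @export
calibrationGain <- function(tone) {
  stopifnot(is(tone, "CalibrationTone"))
  r <- .rms(tone@samples)
  if (r <= 0) stop("calibration tone is silent (zero RMS)")
  tone@referenceSplDb - 20 * log10(r)
}

#' Sound pressure level of a selected call
#'
#' RMS level of the samples in `[begin_s, end_s)` converted to dB SPL with the
#' calibration gain: `SPL = gain + 20*log10(RMS)`.
#'
#' @param rec a [CalibratedRecording-class].
#' @param sel one selection: a list/row with `begin_s` and `end_s`.
#' @param gain calibration gain from [calibrationGain()].
#' @return SPL in dB SPL RMS.
#' @export
callSpl <- function(rec, sel, gain) {
  x <- sliceSelection(rec, sel)
  r <- .rms(x)
  if (r <= 0) stop("selection has zero RMS; cannot compute SPL")
  gain + 20 * log10(r)
}

#' Extract the sample slice of one selection
#'
#' @inheritParams callSpl
#' @return numeric sample vector for `[begin_s, end_s)`.
#' @export
sliceSelection <- function(rec, sel) {
  sr <- rec@sampleRate
  eps <- 1e-9
  i0 <- floor(sel$begin_s * sr + eps) + 1L
  i1 <- ceiling(sel$end_s * sr - eps)
  if (sel$begin_s < 0 || i1 > length(rec@samples)) {
    stop("selection extends beyond the recording")
  }
  rec@samples[i0:min(i1, length(rec@samples))]
}

#' Power-subtraction noise correction of a measured level
#'
#' Removes background-noise power from a signal+noise level:
#' `10*log10(10^(splSn/10) - 10^(splN/10))`. The analysis pipeline applies
#' this only when the signal-to-noise ratio falls below 10 dB; above that the
#' correction is under 0.5 dB and modifications are not justified.
#'
#' @param splSn measured level of signal + noise, dB.
#' @param splN level of background noise alone, dB.
#' @return noise-corrected signal level, dB.
#' @examples
#' noiseCorrect(50, 40)      # 49.54
#' noiseCorrect(43.01, 40)   # ~40: equal signal and noise powers
#' @export
noiseCorrect <- function(splSn, splN) {
  if (splSn <= splN) {
    stop("signal+noise level must exceed noise level (no positive ",
         "signal power to recover)")
  }
  10 * log10(10^(splSn / 10) - 10^(splN / 10))
}

#' Spherical (geometric) transmission loss
#'
#' The level decrease expected from spherical spreading of a point source,
#' `20*log10(dFar/dRef)` — about 6 dB per distance doubling.
#'
#' @param dFarM far distance in metres.
#' @param dRefM reference distance in metres (default 0.25).
#' @return loss in dB.
#' @export
sphericalLoss <- function(dFarM, dRefM = 0.25) {
  if (any(dFarM <= 0) || dRefM <= 0) stop("distances must be positive")
  20 * log10(dFarM / dRefM)
}

#' Excess attenuation beyond spherical spreading
#'
#' The actual transmission loss (reference-distance SPL minus far SPL) minus
#' the spherical prediction. Positive values mean the sound attenuated faster
#' than geometric spreading (scattering, ground effects, absorption);
#' negative values, slower.
#'
#' @param splRef SPL at the reference distance, dB.
#' @param splFar SPL at the far microphone, dB.
#' @param dFarM far distance in metres.
#' @param dRefM reference distance in metres (default 0.25).
#' @return excess attenuation in dB.
#' @export
excessAttenuation <- function(splRef, splFar, dFarM, dRefM = 0.25) {
  if (any(dFarM <= dRefM)) {
    stop("far distance must exceed the reference distance")
  }
  (splRef - splFar) - sphericalLoss(dFarM, dRefM)
}
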