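# shared fixture builders; everything is generated in code

makeRec <- function(samples, sr = 44100, distanceCm = NA_real_,
                    individual = "i1", species = "sp", arrayId = 1L) {
  new("CalibratedRecording", samples = samples, sampleRate = sr,
      distanceCm = distanceCm, individual = individual, species = species,
      arrayId = arrayId, channel = 0L)
}

makeTone <- function(samples, sr = 44100, ref = 93.8) {
  new("CalibrationTone", samples = samples, sampleRate = sr,
      referenceSplDb = ref)
}

sine <- function(freqHz, nSamples, sr = 44100, amp = 1) {
  amp * sin(2 * pi * freqHz * (0:(nSamples - 1)) / sr)
}

wholeSel <- function(rec) {
  list(begin_s = 0, end_s = length(samples(rec)) / sampleRate(rec),
       call_index = 1L)
}

# spectrum object with planted linear amplitudes
specOfAmps <- function(amps, freqs = seq(0, by = 100, length.out = length(amps))) {
  new("CallSpectrum", freqsHz = freqs,
      levelsDb = 20 * log10(amps / max(amps)))
}

# toy exponential TrendModel without an underlying fit
expModel <- function(a, b, cc) {
  new("TrendModel", family = "exponential", fixed = c(a = a, b = b, c = cc),
      sigmaU = 0, sigmaE = 1, logLik = 0, nObs = 0L, nGroups = 0L,
      response = "spl_db", fit = NULL)
}
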