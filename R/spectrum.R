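#' CallSpectrum: a single-frame power spectrum
#'
#' Magnitude spectrum of one analysis frame, on an ascending frequency grid
#' with bin width `sampleRate / nFft`, in dB relative to the strongest bin
#' (the maximum level is 0 dB).
#'
#' @slot freqsHz ascending frequency grid, Hz.
#' @slot levelsDb relative levels, dB (max 0).
#' @export
setClass("CallSpectrum",
  representation(freqsHz = "numeric", levelsDb = "numeric")
)

setValidity("CallSpectrum", function(object) {
  msg <- character()
  if (length(object@freqsHz) != length(object@levelsDb)) {
    msg <- c(msg, "freqsHz and levelsDb must have equal length")
  }
  if (is.unsorted(object@freqsHz, strictly = TRUE)) {
    msg <- c(msg, "freqsHz must be strictly ascending")
  }
  if (length(object@levelsDb) &&
      abs(max(object@levelsDb) - 0) > 1e-9) {
    msg <- c(msg, "levelsDb must be normalized to a 0 dB maximum")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CallSpectrum", function(object) {
  cat(sprintf(
    "CallSpectrum: %d bins, %.2f Hz resolution, peak at %.1f Hz\n",
    length(object@freqsHz), object@freqsHz[2] - object@freqsHz[1],
    object@freqsHz[which.max(object@levelsDb)]
  ))
})

#' Single-frame power spectrum of a call
#'
#' Computes the magnitude spectrum of one Hann-windowed frame of `nFft`
#' samples centred at `begin_s + atFraction * duration` of the selection.
#' The harmonic tonal call is analysed at two thirds of the call duration
#' with a 512-point frame (86.13 Hz / 11.61 ms at 44.1 kHz); the pulsed call
#' at mid-call with a 440-point frame (100.23 Hz / 9.98 ms at 44.1 kHz).
#'
#' @param rec a [CalibratedRecording-class].
#' @param sel one selection (`begin_s`, `end_s`).
#' @param atFraction where in the call to place the frame centre, fraction of
#'   the call duration in (0, 1).
#' @param nFft frame length in samples (512 or 440 in the canonical settings).
#' @param window `"hann"` (default) or `"rectangular"`.
#' @return a [CallSpectrum-class] with `nFft/2 + 1` bins (DC to Nyquist),
#'   normalized so the strongest bin is 0 dB.
#' @export
powerSpectrum <- function(rec, sel, atFraction, nFft,
                          window = c("hann", "rectangular")) {
  window <- match.arg(window)
  sr <- rec@sampleRate
  start <- .frameStart(sel$begin_s, sel$end_s, sr, atFraction, nFft)
  if (start < 1L || start + nFft - 1L > length(rec@samples)) {
    stop("analysis frame extends beyond the recording")
  }
  frame <- rec@samples[start:(start + nFft - 1L)]
  .frameSpectrum(frame, sr, window)
}

## Windowed magnitude spectrum of one frame, normalized to 0 dB peak.
## Shared by powerSpectrum and the synthetic calibration loops so both
## measure through the identical code path.
.frameSpectrum <- function(frame, sr, window = "hann") {
  nFft <- length(frame)
  if (window == "hann") {
    frame <- frame * 0.5 * (1 - cos(2 * pi * (0:(nFft - 1)) / (nFft - 1)))
  }
  mag <- Mod(fft(frame))[seq_len(nFft %/% 2 + 1L)]
  peak <- max(mag)
  if (peak <= 0) stop("frame is silent; spectrum undefined")
  mag <- pmax(mag, peak * 1e-15)  # floor at -300 dB to keep levels finite
  new("CallSpectrum",
      freqsHz = (seq_len(nFft %/% 2 + 1L) - 1L) * sr / nFft,
      levelsDb = 20 * log10(mag / peak))
}

## Frame start index for a selection/fraction/nFft combination (1-based).
## Computed from integer sample counts (half-up rounding) so the frame
## position is exactly invariant to where the call sits inside a longer
## recording.
.frameStart <- function(beginS, endS, sr, atFraction, nFft) {
  b <- floor(beginS * sr + 0.5)
  durSamp <- floor((endS - beginS) * sr + 0.5)
  centre <- b + floor(atFraction * durSamp + 0.5)
  centre - floor(nFft / 2) + 1L
}

#' Harmonic peak frequencies and levels
#'
#' Locates, within each of three disjoint ascending frequency bands, the bin
#' of maximum level — the first (F1), second (F2) and third (F3) harmonic of
#' a tonal call. Ties at equal level break toward the lower-frequency bin.
#'
#' @param spec a [CallSpectrum-class].
#' @param bands list of three `c(lo, hi)` intervals in Hz. The defaults are
#'   centred on the harmonic means of the tonal study call (791, 1492,
#'   2198 Hz).
#' @return a list with `f1_hz`..`f3_hz`, `l1_db`..`l3_db`, and the degradation
#'   ratios `f2f1_db` (= l2 - l1) and `f2f3_db` (= l2 - l3).
#' @export
harmonicPeaks <- function(spec,
                          bands = list(c(400, 1100), c(1100, 1800),
                                       c(1800, 2600))) {
  stopifnot(is(spec, "CallSpectrum"), length(bands) == 3L)
  lo <- vapply(bands, `[`, numeric(1), 1L)
  hi <- vapply(bands, `[`, numeric(1), 2L)
  if (is.unsorted(c(rbind(lo, hi)))) {
    stop("bands must be disjoint and ascending")
  }
  f <- numeric(3)
  l <- numeric(3)
  for (k in 1:3) {
    idx <- which(spec@freqsHz >= lo[k] & spec@freqsHz <= hi[k])
    if (!length(idx)) stop(sprintf("band %d contains no spectrum bins", k))
    best <- idx[which.max(spec@levelsDb[idx])]  # which.max: first (lowest) bin
    f[k] <- spec@freqsHz[best]
    l[k] <- spec@levelsDb[best]
  }
  list(f1_hz = f[1], f2_hz = f[2], f3_hz = f[3],
       l1_db = l[1], l2_db = l[2], l3_db = l[3],
       f2f1_db = l[2] - l[1], f2f3_db = l[2] - l[3])
}

#' Spectral cross-correlation between two spectra
#'
#' Zero-lag Pearson correlation of two spectra on identical frequency grids,
#' computed on linear amplitudes (default) or on the dB levels. Comparing the
#' spectrum of a call at a far microphone against the 0.25 m reference indexes
#' spectral degradation: identical shapes give 1, and the value declines as
#' the far spectrum is distorted by frequency-dependent attenuation and noise.
#'
#' @param specRef,specFar [CallSpectrum-class] objects on the same grid.
#' @param onDb correlate dB levels instead of linear amplitudes (default
#'   FALSE, the linear-amplitude convention).
#' @return Pearson correlation in \[-1, 1\]; symmetric in its arguments.
#' @export
spectralCrossCorrelation <- function(specRef, specFar, onDb = FALSE) {
  stopifnot(is(specRef, "CallSpectrum"), is(specFar, "CallSpectrum"))
  if (length(specRef@freqsHz) != length(specFar@freqsHz) ||
      any(abs(specRef@freqsHz - specFar@freqsHz) > 1e-6)) {
    stop("spectra must share an identical frequency grid")
  }
  a <- if (onDb) specRef@levelsDb else 10^(specRef@levelsDb / 20)
  b <- if (onDb) specFar@levelsDb else 10^(specFar@levelsDb / 20)
  if (sd(a) == 0 || sd(b) == 0) {
    stop("constant spectrum: cross-correlation undefined")
  }
  stats::cor(a, b)
}

#' Amplitude ratio between two spectrum frequencies
#'
#' Level at the bin nearest `fLoHz` minus level at the bin nearest `fHiHz`,
#' in dB. With the canonical 440-point frame at 44.1 kHz the nearest bins to
#' 1 and 2 kHz fall at 1002.3 and 2004.5 Hz.
#'
#' @param spec a [CallSpectrum-class].
#' @param fLoHz,fHiHz the two frequencies, Hz (defaults 1000 and 2000).
#' @return ratio in dB.
#' @export
bandRatio <- function(spec, fLoHz = 1000, fHiHz = 2000) {
  nyq <- max(spec@freqsHz)
  if (fLoHz > nyq || fHiHz > nyq) {
    stop("requested frequency exceeds the Nyquist frequency")
  }
  iLo <- which.min(abs(spec@freqsHz - fLoHz))
  iHi <- which.min(abs(spec@freqsHz - fHiHz))
  spec@levelsDb[iLo] - spec@levelsDb[iHi]
}
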