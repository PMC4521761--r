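## Species call profiles. The two canonical profiles describe the
## advertisement calls of two syntopic austral-forest frogs: a tonal harmonic
## call (Eupsophus calcaratus-like) and a pulsed call (E. emiliopugini-like).
## Each carries the fitted distance-trend equations (distance in cm) that the
## synthetic generator uses as planted ground truth.

#' Species call profile
#'
#' Bundles the waveform recipe (call kind, duration, spectral content,
#' analysis-frame settings) and the per-feature distance trends used as the
#' forward model by the synthetic generator. Trends are given as
#' `list(family, a, b, c)` with distance in cm: `linear` is `a + b*dist`,
#' `quadratic` is `a + b*dist + c*dist^2`, `exponential` is
#' `a + b*exp(-c*dist)`. Each trend may also carry `sigmaU` and `sigmaE`, the
#' default random-intercept and residual SDs (in the feature's own units)
#' used by the analytic feature simulator.
#'
#' @param species species label.
#' @param callKind `"harmonic"` or `"pulsed"`.
#' @param durationMs mean call duration, ms.
#' @param durationRangeMs low/high duration range, ms.
#' @param harmonicsHz up to three harmonic frequencies (harmonic kind), Hz.
#' @param sourceF2F1Db,sourceF2F3Db source-level harmonic ratios, dB
#'   (harmonic kind).
#' @param dominantHz carrier frequency (pulsed kind), Hz.
#' @param pulseRateHz pulse repetition rate (pulsed kind), pulses/s.
#' @param peakTimeFraction position of the amplitude peak within the call.
#' @param nFft analysis-frame length for this species' spectra.
#' @param atFraction analysis-frame centre as a fraction of call duration.
#' @param bands harmonic search bands (harmonic kind).
#' @param trends named list of per-feature trend specifications.
#' @return a list of class `speciesProfile`.
#' @seealso [harmonicProfile()], [pulsedProfile()], [trendValue()]
#' @export
speciesProfile <- function(species, callKind, durationMs, durationRangeMs,
                           harmonicsHz = NULL, sourceF2F1Db = 35,
                           sourceF2F3Db = 10, dominantHz = NULL,
                           pulseRateHz = NULL, peakTimeFraction = 0.5,
                           nFft = 512L, atFraction = 0.5,
                           bands = list(c(400, 1100), c(1100, 1800),
                                        c(1800, 2600)),
                           trends = list()) {
  stopifnot(callKind %in% c("harmonic", "pulsed"), durationMs > 0)
  for (tr in trends) {
    stopifnot(tr$family %in% c("linear", "quadratic", "exponential"),
              all(is.finite(unlist(tr[c("a", "b")]))))
  }
  structure(
    list(species = species, callKind = callKind, durationMs = durationMs,
         durationRangeMs = durationRangeMs, harmonicsHz = harmonicsHz,
         sourceF2F1Db = sourceF2F1Db, sourceF2F3Db = sourceF2F3Db,
         dominantHz = dominantHz, pulseRateHz = pulseRateHz,
         peakTimeFraction = peakTimeFraction, nFft = as.integer(nFft),
         atFraction = atFraction, bands = bands, trends = trends),
    class = "speciesProfile"
  )
}

#' Default harmonic-call species profile
#'
#' A tonal single-note call averaging 285 ms with three harmonics near 791,
#' 1492 and 2198 Hz, the second harmonic dominant (the first and third about
#' 35 and 10 dB below it at the source), peaking at two thirds of its
#' duration. Spectra are analysed there with a 512-point frame. Distance
#' trends: exponential SPL decay `35.42 + 40.25*exp(-0.00336*dist)`, linear
#' excess-attenuation growth, linear declines of spectral cross-correlation
#' and of the F2/F1 ratio, and a quadratic F2/F3 ratio with an interior
#' maximum.
#'
#' @return a `speciesProfile`.
#' @export
harmonicProfile <- function() {
  speciesProfile(
    species = "E_calcaratus", callKind = "harmonic",
    durationMs = 285, durationRangeMs = c(247, 356),
    harmonicsHz = c(791, 1492, 2198),
    sourceF2F1Db = 35, sourceF2F3Db = 10,
    peakTimeFraction = 2 / 3, nFft = 512L, atFraction = 2 / 3,
    trends = list(
      spl  = list(family = "exponential", a = 35.42, b = 40.25, c = 0.00336,
                  sigmaU = 2, sigmaE = 1),
      ea   = list(family = "linear", a = 0.0263, b = 0.0076,
                  sigmaU = 0.5, sigmaE = 1),
      cc   = list(family = "linear", a = 0.95940, b = -0.00040,
                  sigmaU = 0.01, sigmaE = 0.02),
      f2f1 = list(family = "linear", a = 30.50, b = -0.02688,
                  sigmaU = 1, sigmaE = 1.5),
      f2f3 = list(family = "quadratic", a = 5.05, b = 0.03493, c = -0.00004,
                  sigmaU = 1, sigmaE = 1.5)
    )
  )
}

#' Default pulsed-call species profile
#'
#' A pulsed call averaging 245 ms with a 1138 Hz dominant frequency,
#' amplitude-modulated at 50 pulses/s (about 85% modulation depth near the
#' source), peaking at mid-call where spectra are analysed with a 440-point
#' frame. Distance trends: exponential SPL decay
#' `47.39 + 37.60*exp(-0.00397*dist)`, linear excess-attenuation growth,
#' linear declines of cross-correlation and modulation depth, and a quadratic
#' 1-2 kHz amplitude ratio with an interior maximum.
#'
#' @return a `speciesProfile`.
#' @export
pulsedProfile <- function() {
  speciesProfile(
    species = "E_emiliopugini", callKind = "pulsed",
    durationMs = 245, durationRangeMs = c(127, 293),
    dominantHz = 1138, pulseRateHz = 50,
    peakTimeFraction = 0.5, nFft = 440L, atFraction = 0.5,
    trends = list(
      spl  = list(family = "exponential", a = 47.39, b = 37.60, c = 0.00397,
                  sigmaU = 2, sigmaE = 1),
      ea   = list(family = "linear", a = 0.34902, b = 0.00628,
                  sigmaU = 0.5, sigmaE = 1),
      cc   = list(family = "linear", a = 0.96128, b = -0.00018,
                  sigmaU = 0.01, sigmaE = 0.02),
      r12k = list(family = "quadratic", a = 29.07, b = 0.02329, c = -0.00003,
                  sigmaU = 1, sigmaE = 1.5),
      md   = list(family = "linear", a = 84.46, b = -0.01004,
                  sigmaU = 1, sigmaE = 2)
    )
  )
}

#' Evaluate a profile trend at given distances
#'
#' @param profile a `speciesProfile`.
#' @param feature trend name (`"spl"`, `"ea"`, `"cc"`, `"f2f1"`, `"f2f3"`,
#'   `"r12k"`, `"md"`).
#' @param distCm distance(s) in cm.
#' @return the planted feature value(s).
#' @export
trendValue <- function(profile, feature, distCm) {
  tr <- profile$trends[[feature]]
  if (is.null(tr)) {
    stop(sprintf("profile '%s' has no trend for feature '%s'",
                 profile$species, feature))
  }
  evalTrend(tr, distCm)
}

#' Evaluate a trend specification
#'
#' @param tr `list(family, a, b, c)`.
#' @param distCm distance(s), cm.
#' @return numeric value(s).
#' @export
evalTrend <- function(tr, distCm) {
  switch(tr$family,
    none = rep(tr$a, length(distCm)),
    linear = tr$a + tr$b * distCm,
    quadratic = tr$a + tr$b * distCm + tr$c * distCm^2,
    exponential = tr$a + tr$b * exp(-tr$c * distCm),
    stop("unknown trend family: ", tr$family)
  )
}

#' Canonical microphone-array distances
#'
#' Array 1 places microphones at 25, 50, 100 and 400 cm from the source;
#' array 2 at 25, 200, 400 and 800 cm. Pooling array 1 with the complementary
#' array-2 distances (200 and 800 cm) gives the six-distance transect used by
#' the continuous-trend analysis.
#'
#' @return named list of numeric distance vectors (cm).
#' @export
studyArrays <- function() {
  list(`1` = c(25, 50, 100, 400), `2` = c(25, 200, 400, 800))
}

#' The pooled six-distance transect (cm)
#' @return numeric vector `c(25, 50, 100, 200, 400, 800)`.
#' @export
studyDistances <- function() c(25, 50, 100, 200, 400, 800)
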