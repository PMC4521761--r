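## Waveform forward model. Calls are synthesised from a species profile and
## rendered at a distance by planting the profile's trend values: broadband
## gain sets SPL, per-harmonic gains set the F2/F1 and F2/F3 ratios (harmonic
## kind), a spectral tilt sets the 1-2 kHz ratio and an envelope-floor lift
## sets modulation depth (pulsed kind). Planting is closed-loop: each knob is
## solved against the package's own extractor, so noise-free rendering
## reproduces the planted values to the extractor's numerical precision.

#' SynthCall: a synthesised call recipe
#'
#' Holds the separable ingredients of a synthetic call so rendering can
#' re-weight them per distance: the envelope-shaped sinusoidal components
#' (harmonic kind) or the carrier, pulse shape and global envelope (pulsed
#' kind).
#'
#' @slot kind `"harmonic"` or `"pulsed"`.
#' @slot sampleRate sampling rate, Hz.
#' @slot components matrix of finished per-component waveforms (one
#'   envelope-shaped sinusoid per column for the harmonic kind; the finished
#'   modulated waveform for the pulsed kind).
#' @slot carrier raw unmodulated carrier (pulsed kind; empty otherwise).
#' @slot pulse pulse-train shape in \[0, 1\] (pulsed kind; empty otherwise).
#' @slot env global amplitude envelope (pulsed kind; empty otherwise).
#' @export
setClass("SynthCall",
  representation(kind = "character", sampleRate = "numeric",
                 components = "matrix", carrier = "numeric",
                 pulse = "numeric", env = "numeric")
)

setMethod("show", "SynthCall", function(object) {
  cat(sprintf("SynthCall (%s): %d samples @ %g Hz, %d component(s)\n",
              object@kind, nrow(object@components), object@sampleRate,
              ncol(object@components)))
})

#' Waveform of a synthetic call at source weights
#' @param call a [SynthCall-class].
#' @return numeric sample vector.
#' @export
callWaveform <- function(call) rowSums(call@components)

.drawDuration <- function(profile, seed) {
  if (is.null(seed)) return(profile$durationMs)
  .withSeed(seed, runif(1, profile$durationRangeMs[1],
                        profile$durationRangeMs[2]))
}

#' Synthesise a harmonic tonal call
#'
#' Sum of up to three sinusoids at the profile's harmonic frequencies with the
#' second harmonic dominant (source ratios `sourceF2F1Db`, `sourceF2F3Db`
#' below it), under an amplitude envelope rising to a peak at
#' `peakTimeFraction` of the call and decaying afterwards. Duration is drawn
#' uniformly from the profile's stated range when a seed is given, else the
#' profile mean is used.
#'
#' @param profile a harmonic `speciesProfile`.
#' @param sampleRate sampling rate, Hz (default 44100).
#' @param seed integer seed for the duration draw (NULL: use the mean).
#' @param durationMs override the call duration, ms.
#' @return a [SynthCall-class].
#' @export
makeHarmonicCall <- function(profile, sampleRate = 44100, seed = NULL,
                             durationMs = NULL) {
  stopifnot(profile$callKind == "harmonic")
  f <- profile$harmonicsHz
  if (any(f >= sampleRate / 2)) {
    stop("harmonic frequency at or above the Nyquist frequency")
  }
  if (is.null(durationMs)) durationMs <- .drawDuration(profile, seed)
  n <- round(durationMs / 1000 * sampleRate)
  t <- (seq_len(n) - 1) / sampleRate
  amps <- c(10^(-profile$sourceF2F1Db / 20), 1,
            10^(-profile$sourceF2F3Db / 20))[seq_along(f)]
  env <- .peakEnvelope(n, profile$peakTimeFraction)
  comp <- vapply(seq_along(f),
                 function(k) amps[k] * env * sin(2 * pi * f[k] * t),
                 numeric(n))
  new("SynthCall", kind = "harmonic", sampleRate = sampleRate,
      components = comp, carrier = numeric(), pulse = numeric(),
      env = numeric())
}

## Attack to 1 at the peak fraction, decay to a small tail afterwards.
.peakEnvelope <- function(n, peakFraction) {
  i <- seq_len(n)
  peak <- max(2, round(peakFraction * n))
  env <- numeric(n)
  env[1:peak] <- sin(pi / 2 * (i[1:peak] - 1) / (peak - 1))^2
  if (peak < n) {
    s <- (i[(peak + 1):n] - peak) / (n - peak)
    env[(peak + 1):n] <- 0.05 + 0.95 * cos(pi / 2 * s)^2
  }
  env
}

#' Synthesise a pulsed call
#'
#' A sinusoidal carrier at the profile's dominant frequency, amplitude
#' modulated by a raised-cosine pulse train at `pulseRateHz` whose modulation
#' floor is solved (against the package's own envelope extractor) so the
#' measured mid-third modulation depth equals `mdTargetPct`. The global
#' envelope is trapezoidal — flat across the middle of the call — so the
#' mid-third depth reflects the pulses, not the call onset/offset.
#'
#' @param profile a pulsed `speciesProfile`.
#' @param sampleRate sampling rate, Hz.
#' @param seed integer seed for the duration draw (NULL: profile mean).
#' @param durationMs override duration, ms.
#' @param mdTargetPct target modulation depth in \[0, 100\] (default: the
#'   profile's modulation-depth trend at the 25 cm reference).
#' @return a [SynthCall-class].
#' @export
makePulsedCall <- function(profile, sampleRate = 44100, seed = NULL,
                           durationMs = NULL, mdTargetPct = NULL) {
  stopifnot(profile$callKind == "pulsed")
  if (profile$pulseRateHz >= profile$dominantHz) {
    stop("pulse rate must be below the carrier frequency")
  }
  if (is.null(mdTargetPct)) mdTargetPct <- trendValue(profile, "md", 25)
  if (mdTargetPct < 0 || mdTargetPct > 100) {
    stop("modulation-depth target must lie in [0, 100]")
  }
  if (is.null(durationMs)) durationMs <- .drawDuration(profile, seed)
  n <- round(durationMs / 1000 * sampleRate)
  t <- (seq_len(n) - 1) / sampleRate
  ## weak second harmonic gives the upper band real content to shape
  carrier <- sin(2 * pi * profile$dominantHz * t) +
    10^(-15 / 20) * sin(2 * pi * 2 * profile$dominantHz * t)
  pulse <- (1 - cos(2 * pi * profile$pulseRateHz * t)) / 2
  env <- .trapezoidEnvelope(n)
  call <- new("SynthCall", kind = "pulsed", sampleRate = sampleRate,
              components = matrix(carrier, ncol = 1), carrier = carrier,
              pulse = pulse, env = env)
  fl <- .solveModFloor(call, mdTargetPct)
  call@components[, 1] <- .pulsedWaveform(call, fl)
  call
}

.trapezoidEnvelope <- function(n) {
  ramp <- max(2, round(n / 6))
  env <- rep(1, n)
  env[1:ramp] <- seq(0, 1, length.out = ramp)
  env[(n - ramp + 1):n] <- seq(1, 0, length.out = ramp)
  env
}

.pulsedWaveform <- function(call, modFloor, tiltDbPerKhz = 0) {
  x <- call@carrier * call@env *
    (modFloor + (1 - modFloor) * call@pulse)
  if (tiltDbPerKhz != 0) x <- .applyTilt(x, call@sampleRate, tiltDbPerKhz)
  x
}

## Frequency-proportional dB gain anchored at 1 kHz (0 dB there), applied
## only within the call band: outside [loHz, hiHz] the gain is clamped to its
## band-edge value so numerical leakage far from the call content is never
## amplified.
.applyTilt <- function(x, sampleRate, tiltDbPerKhz, loHz = 200, hiHz = 4000) {
  n <- length(x)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * sampleRate / n
  fEff <- pmin(pmax(abs(f), loHz), hiHz)
  g <- 10^(tiltDbPerKhz * (fEff - 1000) / 1000 / 20)
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

.measureMd <- function(x, sampleRate) {
  rec <- new("CalibratedRecording", samples = x, sampleRate = sampleRate)
  sel <- list(begin_s = 0, end_s = length(x) / sampleRate)
  callModulationDepth(rec, sel)
}

.solveModFloor <- function(call, target, tilt = 0) {
  md <- function(fl) .measureMd(.pulsedWaveform(call, fl, tilt),
                                call@sampleRate)
  md0 <- md(0)
  md1 <- md(1)
  if (target >= md0) return(0)
  if (target <= md1) return(1)
  uniroot(function(fl) md(fl) - target, c(0, 1), tol = 1e-12)$root
}

#' Render a synthetic call at a distance
#'
#' Applies the profile's planted trends at `distanceCm`: per-harmonic gains so
#' the extracted F2/F1 and F2/F3 ratios equal their trends (harmonic kind), a
#' spectral tilt so the extracted 1-2 kHz ratio equals its quadratic trend
#' and an envelope-floor lift so the extracted mid-third modulation depth
#' equals its linear trend (pulsed kind), then a broadband gain so the
#' extracted SPL equals `spl trend + interceptSplDb + a residual draw`.
#' Optionally adds band-limited (200-4000 Hz) Gaussian noise at a stated SPL,
#' which is what erodes spectral cross-correlation at far distances.
#'
#' All planting is solved against the package's own extractor, so with zero
#' intercepts/residuals and no noise the extracted features reproduce the
#' trend values to numerical precision.
#'
#' @param call a [SynthCall-class].
#' @param profile the `speciesProfile` the call came from.
#' @param distanceCm rendering distance, cm (>= 25).
#' @param interceptSplDb,interceptMdPct the individual's random intercepts.
#' @param sigmaESplDb,sigmaEMdPct residual SDs for the per-call draws.
#' @param noiseSplDb SPL of added background noise (NA: none).
#' @param gainDb calibration gain mapping sample RMS to dB SPL (default: the
#'   canonical study tone, see [studyGainDb()]).
#' @param seed integer seed for the residual and noise draws.
#' @return list with `samples`, and `truth`: the planted feature values
#'   (`spl_db`, `f2f1_db`, `f2f3_db`, `r12k_db`, `md_pct` as applicable).
#' @export
renderAtDistance <- function(call, profile, distanceCm,
                             interceptSplDb = 0, interceptMdPct = 0,
                             sigmaESplDb = 0, sigmaEMdPct = 0,
                             noiseSplDb = NA_real_,
                             gainDb = studyGainDb(), seed = NULL) {
  if (distanceCm < 25) stop("rendering distances start at the 25 cm reference")
  sr <- call@sampleRate
  draws <- .withSeed(seed, rnorm(3))
  splTarget <- trendValue(profile, "spl", distanceCm) + interceptSplDb +
    sigmaESplDb * draws[1]
  truth <- list(spl_db = splTarget)
  if (call@kind == "harmonic") {
    truth$f2f1_db <- trendValue(profile, "f2f1", distanceCm)
    truth$f2f3_db <- trendValue(profile, "f2f3", distanceCm)
    x <- .solveHarmonicWeights(call, profile, truth$f2f1_db, truth$f2f3_db)
  } else {
    truth$md_pct <- min(100, max(0,
      trendValue(profile, "md", distanceCm) + interceptMdPct +
        sigmaEMdPct * draws[2]))
    truth$r12k_db <- trendValue(profile, "r12k", distanceCm)
    x <- .solvePulsedShape(call, profile, truth$md_pct, truth$r12k_db)
  }
  x <- x * 10^((splTarget - gainDb - 20 * log10(.rms(x))) / 20)
  if (is.finite(noiseSplDb)) {
    if (splTarget < noiseSplDb - 20) {
      warning("planted SPL more than 20 dB below the noise floor; ",
              "the rendered call will be noise-dominated")
    }
    noise <- bandNoise(length(x), sr, noiseSplDb, gainDb,
                       seed = if (is.null(seed)) NULL else seed + 1L)
    x <- x + noise
  }
  list(samples = x, truth = truth)
}

## Iterative per-harmonic gain calibration against the extractor. The
## analysis frame is precomputed once; each iteration re-measures only it.
.solveHarmonicWeights <- function(call, profile, f2f1Target, f2f3Target) {
  w <- c(1, 1, 1)
  sr <- call@sampleRate
  n <- nrow(call@components)
  start <- .frameStart(0, n / sr, sr, profile$atFraction, profile$nFft)
  idx <- start:(start + profile$nFft - 1L)
  frameComp <- call@components[idx, , drop = FALSE]
  for (iter in 1:80) {
    spec <- .frameSpectrum(as.numeric(frameComp %*% w), sr)
    hp <- harmonicPeaks(spec, profile$bands)
    d1 <- hp$f2f1_db - f2f1Target
    d3 <- hp$f2f3_db - f2f3Target
    if (abs(d1) < 1e-11 && abs(d3) < 1e-11) break
    w[1] <- w[1] * 10^(d1 / 20)
    w[3] <- w[3] * 10^(d3 / 20)
  }
  as.numeric(call@components %*% w)
}

## Joint envelope-floor + tilt calibration for the pulsed call. The waveform
## is linear in the floor, x(fl) = fl*A + (1-fl)*B with A the unpulsed and B
## the fully pulsed waveform, and the tilt is a diagonal frequency-domain
## gain, so both solves reuse the cached FFTs of A and B on a padded fast
## length.
.solvePulsedShape <- function(call, profile, mdTarget, r12kTarget) {
  sr <- call@sampleRate
  n <- length(call@carrier)
  A <- call@carrier * call@env
  B <- A * call@pulse
  m <- stats::nextn(n, 2)
  FA <- fft(c(A, numeric(m - n)))
  FB <- fft(c(B, numeric(m - n)))
  f <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) * sr / m
  fEff <- pmin(pmax(abs(f), 200), 4000)
  gainAt <- function(s) 10^(s * (fEff - 1000) / 1000 / 20)
  waveAt <- function(fl, s) {
    X <- fl * FA + (1 - fl) * FB
    if (s != 0) X <- X * gainAt(s)
    Re(fft(X, inverse = TRUE))[seq_len(n)] / m
  }
  start <- .frameStart(0, n / sr, sr, profile$atFraction, profile$nFft)
  idx <- start:(start + profile$nFft - 1L)
  measureR12k <- function(x) bandRatio(.frameSpectrum(x[idx], sr))
  tilt <- 0
  fl <- 0.15
  for (iter in 1:10) {
    mdOf <- function(g) .measureMd(waveAt(g, tilt), sr)
    fl <- if (mdTarget >= mdOf(0)) 0 else if (mdTarget <= mdOf(1)) 1 else {
      uniroot(function(g) mdOf(g) - mdTarget, c(0, 1), tol = 1e-13)$root
    }
    tilt <- uniroot(function(s) measureR12k(waveAt(fl, s)) - r12kTarget,
                    c(-80, 80), tol = 1e-12)$root
    x <- waveAt(fl, tilt)
    if (abs(.measureMd(x, sr) - mdTarget) < 1e-9 &&
        abs(measureR12k(x) - r12kTarget) < 1e-9) break
  }
  x
}

#' Band-limited Gaussian noise at a stated SPL
#'
#' White Gaussian noise restricted (by FFT masking) to the 200-4000 Hz band
#' of the study calls, scaled so its RMS maps to `noiseSplDb` under the given
#' calibration gain.
#'
#' @param n number of samples.
#' @param sampleRate sampling rate, Hz.
#' @param noiseSplDb target noise level, dB SPL.
#' @param gainDb calibration gain.
#' @param loHz,hiHz band edges, Hz.
#' @param seed integer seed.
#' @return numeric sample vector.
#' @export
bandNoise <- function(n, sampleRate, noiseSplDb, gainDb = studyGainDb(),
                      loHz = 200, hiHz = 4000, seed = NULL) {
  .withSeed(seed, {
    m <- stats::nextn(n, 2)  # pad to a fast FFT length, keep the first n
    w <- rnorm(m)
    f <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) * sampleRate / m
    keep <- abs(f) >= loHz & abs(f) <= hiHz
    x <- (Re(fft(fft(w) * keep, inverse = TRUE)) / m)[seq_len(n)]
    x * 10^((noiseSplDb - gainDb - 20 * log10(.rms(x))) / 20)
  })
}

#' Calibration gain implied by the canonical study tone
#'
#' The synthetic study records its calibrator as a 1 kHz sine of amplitude
#' 0.1 (RMS 0.1/sqrt(2)) representing 93.8 dB SPL RMS, giving
#' `G = 93.8 - 20*log10(0.1/sqrt(2))`.
#'
#' @param referenceSplDb tone level, dB SPL RMS.
#' @param toneAmplitude tone amplitude in sample units.
#' @return the gain in dB.
#' @export
studyGainDb <- function(referenceSplDb = 93.8, toneAmplitude = 0.1) {
  referenceSplDb - 20 * log10(toneAmplitude / sqrt(2))
}

#' Generate a complete synthetic propagation study
#'
#' Writes, under `outDir`, a calibration tone, per-individual multi-channel
#' recordings for both microphone arrays (each channel one distance, with
#' `callsPerSubject` calls at shared times across channels, as if recorded
#' simultaneously), per-array selection tables, a study config, and a
#' ground-truth table of every planted feature value.
#'
#' Defaults reproduce the canonical study design: 15 harmonic-call and 17
#' pulsed-call individuals, two arrays (25/50/100/400 cm and 25/200/400/800
#' cm), ten calls per subject, random intercepts of SD 2 (dB for SPL,
#' percentage points for modulation depth) and residual SD 1 on the same
#' scales. Background noise at `noiseSplDb` fills each recording; it creates
#' the low signal-to-noise regime at the farthest distance for the
#' harmonic-call species and erodes spectral cross-correlation with distance.
#'
#' @param outDir output directory (created).
#' @param profiles list of `speciesProfile`s to generate.
#' @param nIndividuals named integer vector of individuals per species label,
#'   or a single integer applied to all profiles.
#' @param callsPerSubject calls per subject per channel (default 10).
#' @param arrays named list of per-array distance vectors, cm.
#' @param sigmaU random-intercept SD (dB for SPL; points for MD).
#' @param sigmaE residual SD per call (same scales).
#' @param noiseSplDb background-noise SPL: a single level (dB), a named
#'   vector keyed by distance (cm), the string `"calibrated"` for the stored
#'   per-distance tables that make extracted cross-correlation track the CC
#'   trends (see [defaultNoiseTable()]), or NA for noise-free rendering.
#' @param sampleRate sampling rate, Hz.
#' @param seed single study seed; all randomness is split from it per
#'   (species, individual, array, call) so any file is reproducible.
#' @param gapS silent gap between calls, s.
#' @return invisibly, the ground-truth data.frame (also written as
#'   `truth.csv`).
#' @export
generateStudy <- function(outDir,
                          profiles = list(harmonicProfile(), pulsedProfile()),
                          nIndividuals = c(E_calcaratus = 15L,
                                           E_emiliopugini = 17L),
                          callsPerSubject = 10L,
                          arrays = studyArrays(),
                          sigmaU = 2, sigmaE = 1,
                          noiseSplDb = 36,
                          sampleRate = 44100, seed = 1L, gapS = 0.4) {
  if (length(nIndividuals) == 1L && is.null(names(nIndividuals))) {
    nIndividuals <- setNames(rep(nIndividuals, length(profiles)),
                             vapply(profiles, `[[`, "", "species"))
  }
  if (length(arrays) == 0L || is.null(names(arrays)) ||
      any(vapply(arrays, length, 0L) < 1L)) {
    stop("invalid array specification")
  }
  keep <- vapply(profiles, `[[`, "", "species") %in% names(nIndividuals)
  profiles <- profiles[keep]
  if (!length(profiles)) stop("no profile matches any species in nIndividuals")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  gain <- studyGainDb()
  tone <- 0.1 * sin(2 * pi * 1000 * (0:(sampleRate - 1)) / sampleRate)
  writeWave(tone, sampleRate, file.path(outDir, "tone.wav"),
            format = "float")
  truth <- list()
  for (profile in profiles) {
    sp <- profile$species
    nInd <- nIndividuals[[sp]]
    if (nInd < 1L) stop("no individual count for species ", sp)
    noiseTab <- if (identical(noiseSplDb, "calibrated")) {
      defaultNoiseTable(sp)
    } else {
      noiseSplDb
    }
    noiseAt <- function(d) {
      if (!is.null(names(noiseTab))) {
        v <- noiseTab[as.character(d)]
        if (is.na(v)) stop("no noise level for distance ", d)
        unname(v)
      } else {
        noiseTab
      }
    }
    for (ind in seq_len(nInd)) {
      indId <- sprintf("ind%02d", ind)
      uSpl <- .withSeed(.splitSeed(seed, 1, match(sp, names(nIndividuals)),
                                   ind), rnorm(1, 0, sigmaU))
      uMd <- .withSeed(.splitSeed(seed, 2, match(sp, names(nIndividuals)),
                                  ind), rnorm(1, 0, sigmaU))
      for (arrId in names(arrays)) {
        dists <- arrays[[arrId]]
        calls <- lapply(seq_len(callsPerSubject), function(k) {
          s <- .splitSeed(seed, 3, match(sp, names(nIndividuals)), ind,
                          as.integer(arrId), k)
          if (profile$callKind == "harmonic") {
            makeHarmonicCall(profile, sampleRate, seed = s)
          } else {
            makePulsedCall(profile, sampleRate, seed = s)
          }
        })
        ns <- vapply(calls, function(cl) nrow(cl@components), 0L)
        gap <- round(gapS * sampleRate)
        starts <- gap + cumsum(c(0L, (ns + gap)[-length(ns)])) + 1L
        total <- starts[length(starts)] + ns[length(ns)] - 1L + gap
        arrDir <- file.path(outDir, sp, indId, paste0("array", arrId))
        dir.create(arrDir, recursive = TRUE, showWarnings = FALSE)
        sel <- data.frame(begin_s = (starts - 1L) / sampleRate,
                          end_s = (starts - 1L + ns) / sampleRate)
        writeSelections(sel, file.path(arrDir, "selections.tsv"))
        for (ch in seq_along(dists) - 1L) {
          d <- dists[ch + 1L]
          track <- numeric(total)
          for (k in seq_len(callsPerSubject)) {
            s <- .splitSeed(seed, 4, match(sp, names(nIndividuals)), ind,
                            as.integer(arrId), k, ch)
            r <- renderAtDistance(calls[[k]], profile, d,
                                  interceptSplDb = uSpl,
                                  interceptMdPct = uMd,
                                  sigmaESplDb = sigmaE,
                                  sigmaEMdPct = sigmaE,
                                  gainDb = gain, seed = s)
            idx <- starts[k]:(starts[k] + ns[k] - 1L)
            track[idx] <- r$samples
            truth[[length(truth) + 1L]] <- data.frame(
              species = sp, individual = indId,
              array_id = as.integer(arrId), distance_cm = d,
              call_index = k, channel = ch,
              spl_db = r$truth$spl_db,
              ea_db = if (d > 25) {
                (trendValue(profile, "spl", 25) + uSpl - r$truth$spl_db) -
                  sphericalLoss(d / 100)
              } else NA_real_,
              cc_trend = if (d > 25) trendValue(profile, "cc", d)
                         else NA_real_,
              f2f1_db = r$truth$f2f1_db %||% NA_real_,
              f2f3_db = r$truth$f2f3_db %||% NA_real_,
              r12k_db = r$truth$r12k_db %||% NA_real_,
              md_pct = r$truth$md_pct %||% NA_real_,
              intercept_spl_db = uSpl, intercept_md_pct = uMd,
              duration_ms = 1000 * ns[k] / sampleRate
            )
          }
          nd <- noiseAt(d)
          if (is.finite(nd)) {
            s <- .splitSeed(seed, 5, match(sp, names(nIndividuals)), ind,
                            as.integer(arrId), ch)
            track <- track + bandNoise(total, sampleRate, nd, gain, seed = s)
          }
          writeWave(track, sampleRate,
                    file.path(arrDir, sprintf("ch%d.wav", ch)),
                    format = "float")
        }
      }
    }
  }
  truth <- do.call(rbind, truth)
  write.csv(truth, file.path(outDir, "truth.csv"), row.names = FALSE)
  cfg <- list(
    seed = seed, sample_rate = sampleRate, gain_db = gain,
    noise_spl_db = if (identical(noiseSplDb, "calibrated")) "calibrated"
                   else if (all(is.finite(noiseSplDb))) as.list(noiseSplDb)
                   else NULL,
    sigma_u = sigmaU, sigma_e = sigmaE,
    calls_per_subject = callsPerSubject,
    arrays = lapply(arrays, as.numeric),
    species = lapply(profiles, function(p) {
      list(species = p$species, call_kind = p$callKind,
           n_fft = p$nFft, at_fraction = p$atFraction)
    })
  )
  yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
  invisible(truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
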