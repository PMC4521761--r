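---
title: "Measuring and modelling the propagation of animal calls with sonotrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling the propagation of animal calls with sonotrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonotrend)
```

## The problem

When an animal vocalizes, the signal that reaches a distant receiver is not
the signal that left the source. Geometric (spherical) spreading removes
about 6 dB per distance doubling; scattering, ground effects and atmospheric
absorption remove more ("excess attenuation"); frequency-dependent filtering
and background noise distort the spectrum; and reverberation and noise fill
the amplitude troughs of pulsed signals. How fast these processes erode a
signal determines its *active space*: the distance out to which a
conspecific can still detect it.

`sonotrend` implements a complete measurement-and-modelling pipeline for
studies in which calls of individually identified animals are recorded
*simultaneously* at several known distances with calibrated microphones. The
canonical design it targets is a pair of syntopic austral-forest frogs with
contrasting call structures — a quiet tonal call with three harmonics near
791/1492/2198 Hz, and a louder pulsed call with a ~1138 Hz dominant
frequency — recorded by two four-microphone arrays (25/50/100/400 cm and
25/200/400/800 cm from the calling burrow), with a 93.8 dB SPL RMS
calibration tone tying sample units to sound pressure level.

## Per-call measurements

For each selected call on each channel the extractor computes:

* **SPL** (dB SPL RMS): `gain + 20*log10(RMS)` over the selection, where the
  gain comes from the calibration tone. When the signal-to-noise ratio is
  below 10 dB the background-noise power (measured on a contiguous noise
  interval) is subtracted: `10*log10(10^(L/10) - 10^(N/10))`. Above 10 dB
  SNR the correction is under half a decibel and is not applied.
* **Excess attenuation** (dB): the observed transmission loss from the 25 cm
  reference minus the spherical prediction `20*log10(d / 0.25 m)`. Positive
  values mean faster-than-spherical decay; negative values occur and are
  legitimate (ground or interference gains).
* **Single-frame spectra**: one Hann-windowed frame per call, 512 points for
  the harmonic call (placed at 2/3 of call duration, where its envelope
  peaks; 86.13 Hz and 11.61 ms resolution at 44.1 kHz) and 440 points for
  the pulsed call (mid-call; 100.23 Hz and 9.98 ms). From these:
  harmonic peak frequencies/levels in three search bands (400–1100,
  1100–1800, 1800–2600 Hz) and the F2/F1 and F2/F3 ratios; the 1–2 kHz
  amplitude ratio (nearest bins, 1002.3 and 2004.5 Hz on the 440-point
  grid); and the spectral cross-correlation against the same call's 25 cm
  spectrum.
* **Modulation depth** (%): `100*(max - min)/max` of the block-RMS envelope
  (30-sample non-overlapping blocks) over the middle third of the call.

Three measurement conventions are deliberately pinned down because the
field's software leaves them ambiguous: cross-correlation is zero-lag
Pearson on *linear* amplitudes (a dB-domain variant is available via
`ccOnDb`); modulation depth uses `(max - min)/max`, which is bounded in
[0, 100] and consistent with the 76–85% values typical of pulsed anuran
calls, rather than `(max - min)/(max + min)`, which cannot exceed 100 but
compresses that range; and ties at equal spectral peak level resolve to the
lower-frequency bin. The analysis frame position is computed from integer
sample counts with half-up rounding, so a call yields the same frame whether
it is analysed in isolation or embedded in a longer recording.

## Distance models

All models are random-intercept mixed models — each individual was recorded
at every distance, so observations are not independent. Three analyses are
fitted, mirroring standard practice:

1. **Categorical distance, per array** (`fitFactorModel`): distance as a
   factor, fitted by ML; the distance effect is evaluated by a
   likelihood-ratio test against the intercept-only model; when supported at
   `alpha = 0.05` the model is refitted by REML and *a priori* contrasts of
   each distance against the 25 cm reference are read off with Wald
   intervals Bonferroni-widened to level `1 - alpha/k`.
2. **Continuous distance, pooled transect** (`selectTrend`): all of array 1
   plus the complementary distances of array 2 (200 and 800 cm) give six
   distances from 25 to 800 cm. Candidate trends are *no change*, *linear*
   (`a + b*d`), *quadratic* (`a + b*d + c*d^2`, an "interior extremum" trend
   when the vertex `-b/(2c)` falls inside the transect) and *exponential*
   (`a + b*exp(-c*d)` with the random intercept on `a`). The polynomial
   ladder is tested by nested LRTs (1 df each); the exponential is tested
   against the no-change model (2 df). Distance is carried in cm.
3. **Species comparison** (`compareSpecies`): species, categorical distance
   and their interaction as fixed effects, evaluated by sequential LRTs
   (interaction: full vs additive; each main effect: additive vs the model
   without it).

Polynomial and factor models use `lme4`; the exponential model uses
`nlme::nlme` with self-starting values from the distance means (`a0` the
minimum mean, `b0` the range, `c0` from a log-linear regression of the
excess over `a0`, kept in (1e-6, 1)). Internally polynomials are fitted on
distance in metres for conditioning and reported per cm; the log-likelihood
is unaffected. If the nonlinear mixed fit fails, the fit falls back first to
a fixed-effects nonlinear fit (`sigmaU = 0`) and then to the intercept-only
model, each with a warning.

**Choosing between non-nested 3-parameter families.** The quadratic and the
exponential both add curvature and have the same fixed-parameter count, but
they are not nested, so no LRT orders them. When the quadratic step is
supported, `selectTrend` returns the exponential instead only if its own
test against the no-change model is significant *and* its log-likelihood
exceeds the quadratic's. A decaying exponential response makes the quadratic
step significant essentially always (the curvature is real), and the
exponential then wins on likelihood; a response with a genuine interior
extremum cannot be matched by a monotone exponential, so the quadratic wins.
LRT reference distributions are plain chi-squared with df equal to the
difference in fixed-parameter count; boundary corrections for variance
components are not applied. Optional per-response `log`/`sqrt`
transformations are user configuration, recorded in output metadata, never
auto-selected.

**Active space** (`estimateRange`): a fitted exponential SPL trend is
inverted against a detection threshold `T` (an external input, e.g. the
~58 dB SPL conspecific auditory threshold of the harmonic-call species):
`range = -(1/c) * log((T - a)/b)` for `a < T < SPL(25 cm)`, `Inf` when the
asymptote `a` is at or above `T`, and 0 when the call is already below
threshold at the reference distance (ranges inverting to less than 25 cm
are clamped to 0 — extrapolation toward the source is undefined). For the
default harmonic-call trend and `T = 58` this gives ≈ 172 cm, i.e. an
active space under 2 m. A parametric bootstrap on the fixed-effect
covariance (`rangeCi`) propagates parameter uncertainty; note the model-based
range and a range read off raw per-distance means can differ. The
closed form applies only to the exponential family; for other families the
fitted curve would need numeric root-finding, which is why `estimateRange`
refuses them explicitly.

## The synthetic study generator

Because no recordings ship with the package, `generateStudy` renders a
complete surrogate study whose *planted ground truth is the set of default
trend equations stored in the species profiles* (an exponential SPL decay,
linear EA/CC declines, a linear F2/F1 or MD decline, and a quadratic
F2/F3 or 1–2 kHz ratio). Each call is synthesised from its profile —
a three-harmonic stack with the second harmonic dominant (F1 and F3 about
35 and 10 dB below it at source) under an envelope peaking at 2/3 of the
call, or a 50 pulses/s raised-cosine-modulated carrier with a weak (-15 dB)
second harmonic under a trapezoidal envelope — and rendered at each
microphone distance by solving, against the package's *own extractor*:

* a broadband gain so the extracted SPL equals
  `trend + individual intercept + residual draw`;
* per-harmonic gains so F2/F1 and F2/F3 equal their trends (harmonic kind);
* an envelope-floor lift so mid-third modulation depth equals its trend, and
  a frequency-proportional spectral tilt (in dB, anchored at 1 kHz,
  band-limited to 200–4000 Hz so leakage far from the call content is never
  amplified) so the 1–2 kHz ratio equals its quadratic trend (pulsed kind).

Because every knob is solved through the extractor, noise-free rendering
with zero random effects reproduces the planted values to numerical
precision (float32 WAV storage bounds the on-disk round trip at about
1e-5 dB), which is the package's strongest self-test: any disagreement
between generator and extractor conventions would surface as a closed-loop
error. Pulse rate (not reported for the real species) defaults to
50 pulses/s, giving ~12 visible pulses in a 245 ms call. Call durations are
drawn uniformly from each profile's observed range. Random intercepts (SD 2)
and residual draws (SD 1) apply to SPL in dB and modulation depth in
percentage points; other features inherit correlated variation through the
waveform. All randomness derives from one study seed via counter-based
splitting, so any single file is reproducible in isolation.

**Noise and cross-correlation.** Spectral cross-correlation is *not*
planted; it emerges from band-limited (200–4000 Hz) Gaussian noise added to
each channel. The default floor of 36 dB SPL reproduces the study's SNR
regime — the harmonic call becomes noise-embedded (SNR < 10 dB) at 8 m,
triggering the power-subtraction correction, while the pulsed call stays
clean — but under it CC declines more slowly than the stored linear CC
trends. Matching those trends through noise alone requires noise within a
few dB of the signal even at 50 cm (`calibrateNoiseCC` computes the required
per-distance levels; `defaultNoiseTable` stores them;
`noiseSplDb = "calibrated"` uses them), at the cost of degrading the planted
modulation-depth and SPL fidelity. Real spectra degrade through scattering
and reverberation that this phenomenological forward model does not include,
so one noise table cannot serve all features simultaneously; studies of the
CC trend should use the calibrated table and the analytic simulator should
be used for CC model-recovery work.

**The analytic simulator.** `simulateFeatureTable` bypasses audio entirely
and draws feature values directly from a trend with the random-intercept
structure (`value = trend(d) + u_i + e`), using per-feature default SDs
stored alongside each trend (e.g. 2/1 for SPL in dB, 0.01/0.02 for CC,
1/2 for MD in points). This is the generator used for parameter-recovery and
trend-selection studies: 15 (harmonic) or 17 (pulsed) individuals × 10 calls
across the six study distances (features defined relative to the reference —
EA and CC — use the five far distances), sizes chosen to match the canonical
field design. Recovery checks run 8–20 replicates and require mean estimates
within three Monte-Carlo standard errors of truth; selection checks run 100
replicates and require the planted family back at a ≥ 95% pooled rate,
consistent with the 5% false-positive rate the alpha = 0.05 ladder concedes
at the quadratic step for truly linear responses.

One inconsistency is inherited knowingly: the planted SPL exponential and
the planted EA linear trend cannot both hold exactly (EA is a deterministic
function of SPL and distance), as the underlying fitted equations come from
separate regressions. The waveform generator plants SPL and lets EA emerge;
the analytic simulator draws each feature from its own trend.

## Known limitations

* No physical acoustics: no ray tracing, ground impedance, atmospheric
  absorption or reverberation; degradation is phenomenological.
* The pulsed call's spectrum between its sidebands is synthetic leakage;
  the 1–2 kHz ratio is shaped by an explicit tilt, not by a propagation
  model.
* Random effects are intercepts only (matching the study design's
  convergence constraints); random slopes are out of scope.
* The WAV reader handles PCM 16/24-bit and IEEE float32, mono or
  multi-channel; no compressed codecs or resampling.
* Passing tests on synthetic calls show the measurement and modelling chain
  is internally consistent; they cannot show that real recordings satisfy
  the forward model's assumptions.
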