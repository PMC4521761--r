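# sonotrend

Attenuation and degradation analysis of animal vocalizations recorded at
multiple distances from the emitter.

`sonotrend` is for bioacousticians who record calling animals simultaneously
on calibrated multi-microphone arrays and want to quantify how the signal
decays and degrades with distance — and how far it remains detectable. The
canonical study design it implements is a pair of syntopic frogs with
contrasting advertisement calls (a quiet tonal call with harmonics near
791/1492/2198 Hz and a louder pulsed call with a ~1138 Hz dominant
frequency), recorded at 25–800 cm with a 93.8 dB SPL RMS calibration tone.

## What it computes

**Per-call features** (from WAV recordings + tab-delimited selection tables):

* calibrated sound pressure level, `SPL = gain + 20·log10(RMS)`, with
  power-subtraction noise correction `10·log10(10^(L/10) − 10^(N/10))`
  applied only below 10 dB SNR;
* excess attenuation beyond spherical spreading,
  `EA = (SPL_ref − SPL_far) − 20·log10(d/0.25 m)`;
* single-frame power spectra (Hann, 512 or 440 points), harmonic peaks and
  the F2/F1, F2/F3 and 1–2 kHz amplitude ratios;
* spectral cross-correlation against the 25 cm reference spectrum
  (zero-lag Pearson on linear amplitudes);
* amplitude-modulation depth `100·(max − min)/max` of the block-RMS envelope
  over the middle third of the call.

**Distance models** (random-intercept mixed models; `lme4`/`nlme` underneath):
categorical-distance models with likelihood-ratio tests and
Bonferroni-corrected contrasts against the reference distance; a
continuous-distance trend ladder — no change, linear `a + b·d`, quadratic
`a + b·d + c·d²`, exponential `a + b·e^(−c·d)` — selected by nested LRTs at
α = 0.05; and species × distance interaction models.

**Active space**: inversion of a fitted exponential SPL trend against a
detection threshold `T`, `range = −(1/c)·ln((T − a)/b)`, with a parametric
bootstrap interval.

**Synthetic studies**: `generateStudy()` renders a complete surrogate study
(calibration tone, multi-channel WAVs, selection tables, ground-truth table)
whose planted truth is the set of default trend equations stored in the
species profiles; `simulateFeatureTable()` draws feature tables analytically
from the same trends. Both drive the package's closed-loop validation.

## Worked example

Simulate the pulsed-call species' SPL measurements under the canonical study
conditions (17 individuals × 10 calls at 25–800 cm, random-intercept SD 2 dB,
residual SD 1 dB), fit the exponential decay, and invert it against a 58 dB
SPL detection threshold:

```r
library(sonotrend)

tab <- simulateFeatureTable(pulsedProfile(), "spl", nIndividuals = 17, seed = 1)
m <- fitExponentialTrend(tab, "value")
m
#> TrendModel (exponential) for 'value'
#>   fixed: a=47.332, b=37.717, c=0.0039004
#>   sigma_u=1.82 sigma_e=1.036 logLik=-1527.43 (n=1020, groups=17)

estimateRange(m, 58)
#> ActiveSpaceEstimate: range = 323.7864 cm at threshold 58.0 dB SPL

ci <- rangeCi(m, 58, nBoot = 1000, seed = 1)
cat(sprintf("95%% bootstrap interval: %.0f - %.0f cm\n", ci$lo, ci$hi))
#> 95% bootstrap interval: 303 - 347 cm
```

The fitted asymptote (47.3 dB), decay amplitude (37.7 dB) and rate
(0.0039 per cm) recover the generating trend `47.39 + 37.60·e^(−0.00397·d)`;
at a 58 dB threshold this call carries a bit over 3 m. The same fit for the
quiet tonal call (`harmonicProfile()`, trend `35.42 + 40.25·e^(−0.00336·d)`)
gives a range of about 176 cm — an active space under 2 m:

```r
hm <- fitTrendFamily(simulateFeatureTable(harmonicProfile(), "spl", 15, seed = 1),
                     "value", "exponential")
estimateRange(hm, 58)
#> ActiveSpaceEstimate: range = 175.8452 cm at threshold 58.0 dB SPL
```

A full waveform-level round trip — synthesis, rendering, extraction,
modelling — runs through the pipeline driver:

```r
runPipeline(list(
  seed = 42, out_dir = "runs/demo",
  synth = list(n_individuals = list(E_calcaratus = 4L, E_emiliopugini = 4L),
               calls_per_subject = 3L)
))
```

which writes `features.csv`, per-array factor models and contrasts, selected
trend models, species comparisons, active-space estimates and a
machine-readable `run_report.json` under `runs/demo/`. The same stages are
available as subcommands of the thin CLI in `inst/exec/sonotrend`. See
`vignettes/methods.Rmd` for the modelling details and design choices.

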