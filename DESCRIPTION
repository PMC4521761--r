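Package: sonotrend
Title: Attenuation and Degradation Analysis of Animal Calls Recorded at
    Multiple Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how animal vocalizations attenuate and
    degrade as they propagate from the emitter. Reads calibrated multi-channel
    WAV recordings with selection tables, converts sample units to sound
    pressure level via a reference tone, and measures per-call sound pressure
    level (with power-subtraction noise correction), excess attenuation beyond
    spherical spreading, single-frame power spectra, harmonic peak ratios,
    spectral cross-correlation against a near-source reference, and
    amplitude-modulation depth of pulsed calls. Distance trends are modelled
    with random-intercept mixed models: categorical-distance models with
    Bonferroni-corrected a priori contrasts, a continuous-distance trend
    ladder (none/linear/quadratic/exponential) selected by likelihood-ratio
    tests, and two-species interaction models. A fitted exponential amplitude
    trend can be inverted against a detection threshold to estimate the
    active space of a signal. A synthetic-study generator renders harmonic
    and pulsed calls at the study distances with planted feature trends,
    providing ground truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
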