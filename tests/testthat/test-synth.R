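hp <- harmonicProfile()
pp <- pulsedProfile()

test_that("harmonic call synthesis matches duration and planted spectrum", {
  cl <- makeHarmonicCall(hp, 44100, durationMs = 285)
  n <- nrow(cl@components)
  expect_lt(abs(n - 0.285 * 44100), 1)
  # extractor reads back the planted harmonic frequencies within one bin
  x <- callWaveform(cl)
  rec <- makeRec(x)
  spec <- powerSpectrum(rec, wholeSel(rec), hp$atFraction, hp$nFft)
  pk <- harmonicPeaks(spec, hp$bands)
  expect_lt(abs(pk$f1_hz - 791), 44100 / 512)
  expect_lt(abs(pk$f2_hz - 1492), 44100 / 512)
  expect_lt(abs(pk$f3_hz - 2198), 44100 / 512)
  # degenerate single-harmonic profile gives a pure tone
  one <- hp
  one$harmonicsHz <- 900
  tone <- callWaveform(makeHarmonicCall(one, 44100, durationMs = 100))
  spec1 <- powerSpectrum(makeRec(tone),
                         list(begin_s = 0, end_s = length(tone) / 44100),
                         0.5, 512L)
  expect_lt(abs(spec1@freqsHz[which.max(spec1@levelsDb)] - 900), 44100 / 512)
  bad <- hp
  bad$harmonicsHz <- c(791, 30000)
  expect_error(makeHarmonicCall(bad), "Nyquist")
})

test_that("pulsed call hits its modulation-depth target", {
  cl <- makePulsedCall(pp, 44100, durationMs = 245, mdTargetPct = 85)
  x <- callWaveform(cl)
  rec <- makeRec(x)
  expect_equal(callModulationDepth(rec, wholeSel(rec)), 85, tolerance = 3)
  # target 0 collapses to an (effectively) unmodulated tone
  x0 <- callWaveform(makePulsedCall(pp, 44100, durationMs = 245,
                                    mdTargetPct = 0))
  env0 <- callEnvelope(makeRec(x0),
                       list(begin_s = 245 / 3000, end_s = 2 * 245 / 3000))
  # no pulse structure left beyond carrier-phase ripple
  expect_lt(modulationDepth(env0), 25)
  # target 100 drives the modulation floor to zero
  cl100 <- makePulsedCall(pp, 44100, durationMs = 245, mdTargetPct = 100)
  recF <- makeRec(callWaveform(cl100))
  expect_gt(callModulationDepth(recF, wholeSel(recF)), 97)
  expect_error(makePulsedCall(pp, mdTargetPct = 120), "\\[0, 100\\]")
})

test_that("rendering is deterministic given the seed", {
  cl <- makeHarmonicCall(hp, 44100, seed = 5)
  r1 <- renderAtDistance(cl, hp, 200, sigmaESplDb = 1, noiseSplDb = 40,
                         seed = 17)
  r2 <- renderAtDistance(cl, hp, 200, sigmaESplDb = 1, noiseSplDb = 40,
                         seed = 17)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$truth, r2$truth)
  expect_error(renderAtDistance(cl, hp, 10), "25 cm")
  expect_warning(renderAtDistance(cl, hp, 800, noiseSplDb = 80, seed = 1),
                 "noise-dominated")
})

test_that("noise-free rendering reproduces the planted trends exactly", {
  gain <- studyGainDb()
  cl <- makeHarmonicCall(hp, 44100, seed = 2)
  for (d in c(25, 100, 800)) {
    r <- renderAtDistance(cl, hp, d, gainDb = gain)
    rec <- makeRec(r$samples, distanceCm = d)
    sel <- wholeSel(rec)
    expect_equal(callSpl(rec, sel, gain), trendValue(hp, "spl", d),
                 tolerance = 1e-9)
    pk <- harmonicPeaks(powerSpectrum(rec, sel, hp$atFraction, hp$nFft),
                        hp$bands)
    expect_equal(pk$f2f1_db, trendValue(hp, "f2f1", d), tolerance = 1e-8)
    expect_equal(pk$f2f3_db, trendValue(hp, "f2f3", d), tolerance = 1e-8)
  }
  cp <- makePulsedCall(pp, 44100, seed = 2)
  for (d in c(50, 400)) {
    r <- renderAtDistance(cp, pp, d, gainDb = gain)
    rec <- makeRec(r$samples, distanceCm = d)
    sel <- wholeSel(rec)
    expect_equal(callSpl(rec, sel, gain), trendValue(pp, "spl", d),
                 tolerance = 1e-9)
    expect_equal(callModulationDepth(rec, sel), trendValue(pp, "md", d),
                 tolerance = 1e-6)
    expect_equal(bandRatio(powerSpectrum(rec, sel, pp$atFraction, pp$nFft)),
                 trendValue(pp, "r12k", d), tolerance = 1e-8)
  }
})

test_that("band noise has the requested level and band", {
  gain <- studyGainDb()
  x <- bandNoise(44100, 44100, 50, gain, seed = 4)
  expect_equal(gain + 20 * log10(sqrt(mean(x^2))), 50, tolerance = 1e-9)
  spec <- Mod(fft(x))[1:22050]
  f <- (0:22049)
  inBand <- mean(spec[f >= 200 & f <= 4000]^2)
  outBand <- mean(spec[f > 5000]^2)
  expect_gt(inBand / outBand, 1e3)
  expect_identical(x, bandNoise(44100, 44100, 50, gain, seed = 4))
})

test_that("generateStudy writes a complete, reproducible study tree", {
  dir1 <- withr::local_tempdir()
  truth <- generateStudy(dir1,
                         nIndividuals = c(E_calcaratus = 1L,
                                          E_emiliopugini = 1L),
                         callsPerSubject = 1L, sigmaU = 0.5, sigmaE = 0.3,
                         noiseSplDb = 40, seed = 99)
  # (1 + 1 individuals) x 2 arrays x 4 channels x 1 call
  expect_equal(nrow(truth), 16L)
  expect_true(file.exists(file.path(dir1, "tone.wav")))
  expect_true(file.exists(file.path(dir1, "truth.csv")))
  expect_true(file.exists(file.path(dir1, "config.yaml")))
  expect_true(file.exists(
    file.path(dir1, "E_calcaratus", "ind01", "array1", "ch0.wav")))
  sel <- readSelections(
    file.path(dir1, "E_emiliopugini", "ind01", "array2", "selections.tsv"))
  expect_equal(nrow(sel), 1L)
  # identical seed reproduces identical truth
  dir2 <- withr::local_tempdir()
  truth2 <- generateStudy(dir2,
                          nIndividuals = c(E_calcaratus = 1L,
                                           E_emiliopugini = 1L),
                          callsPerSubject = 1L, sigmaU = 0.5, sigmaE = 0.3,
                          noiseSplDb = 40, seed = 99)
  expect_equal(truth, truth2)
  expect_error(generateStudy(withr::local_tempdir(), arrays = list(),
                             nIndividuals = c(E_calcaratus = 1L)),
               "invalid array")
})

test_that("extraction recovers the planted study truth through files", {
  dir <- withr::local_tempdir()
  truth <- generateStudy(dir,
                         nIndividuals = c(E_calcaratus = 1L,
                                          E_emiliopugini = 1L),
                         callsPerSubject = 2L, sigmaU = 0, sigmaE = 0,
                         noiseSplDb = NA, seed = 12)
  ft <- extractFeatures(dir)
  expect_equal(nrow(ft), nrow(truth))
  m <- merge(ft, truth,
             by = c("species", "individual", "array_id", "distance_cm",
                    "call_index"))
  # float32 storage bounds the reproduction error
  expect_lt(max(abs(m$spl_db.x - m$spl_db.y)), 1e-5)
  expect_lt(max(abs(m$ea_db.x - m$ea_db.y), na.rm = TRUE), 1e-5)
  expect_lt(max(abs(m$f2f1_db.x - m$f2f1_db.y), na.rm = TRUE), 1e-4)
  expect_lt(max(abs(m$f2f3_db.x - m$f2f3_db.y), na.rm = TRUE), 1e-4)
  expect_lt(max(abs(m$r12k_db.x - m$r12k_db.y), na.rm = TRUE), 1e-4)
  expect_lt(max(abs(m$md_pct.x - m$md_pct.y), na.rm = TRUE), 1e-3)
  # without noise, spectra at far microphones stay highly correlated
  expect_gt(min(m$cc, na.rm = TRUE), 0.9)
})

test_that("noisy far-distance calls trigger noise correction as designed", {
  dir <- withr::local_tempdir()
  generateStudy(dir, nIndividuals = c(E_calcaratus = 1L),
                profiles = list(harmonicProfile()),
                callsPerSubject = 2L, sigmaU = 0, sigmaE = 0,
                noiseSplDb = 36, seed = 5)
  ft <- extractFeatures(dir, profiles = list(harmonicProfile()))
  far <- ft[ft$distance_cm == 800, ]
  expect_true(all(far$snr_db < 10))
  expect_true(all(far$spl_corrected))
  near <- ft[ft$distance_cm == 25, ]
  expect_true(all(near$snr_db > 10))
  expect_false(any(near$spl_corrected))
  # corrected SPL is close to the planted level despite the noise
  truth <- readFeatureTable(file.path(dir, "truth.csv"))
  m <- merge(far, truth[truth$distance_cm == 800 & truth$array_id == 2, ],
             by = "call_index")
  expect_lt(max(abs(m$spl_db.x - m$spl_db.y)), 2)
})
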