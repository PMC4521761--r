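test_that("analysis frame grid matches the canonical resolutions", {
  rec <- makeRec(sine(1000, 44100))
  s512 <- powerSpectrum(rec, wholeSel(rec), 0.5, 512L)
  expect_equal(s512@freqsHz[2] - s512@freqsHz[1], 44100 / 512)
  expect_equal(round(44100 / 512, 2), 86.13)
  expect_equal(round(1000 * 512 / 44100, 2), 11.61)
  s440 <- powerSpectrum(rec, wholeSel(rec), 0.5, 440L)
  expect_equal(round(s440@freqsHz[2] - s440@freqsHz[1], 2), 100.23)
  # a pure 1 kHz sine peaks within one bin of 1 kHz, normalized to 0 dB
  peak <- s512@freqsHz[which.max(s512@levelsDb)]
  expect_lt(abs(peak - 1000), 44100 / 512)
  expect_equal(max(s512@levelsDb), 0)
  expect_equal(max(s440@levelsDb), 0)
})

test_that("frame placement is validated against the recording", {
  rec <- makeRec(sine(1000, 600))
  expect_error(powerSpectrum(rec, wholeSel(rec), 0.9, 512L), "beyond")
  expect_error(powerSpectrum(makeRec(rep(0, 2000)),
                             list(begin_s = 0, end_s = 0.04), 0.5, 512L),
               "silent")
})

test_that("harmonic peaks find band maxima with a low-frequency tie-break", {
  freqs <- (0:256) * 44100 / 512
  lv <- rep(-60, 257)
  set.seed(1)
  lv <- lv + runif(257)  # rough noise floor
  plant <- function(fHz, db) {
    i <- which.min(abs(freqs - fHz))
    lv[i] <<- db
  }
  plant(791, -35); plant(1492, 0); plant(2198, -10)
  spec <- new("CallSpectrum", freqsHz = freqs, levelsDb = lv - max(lv))
  hp <- harmonicPeaks(spec)
  expect_lt(abs(hp$f1_hz - 791), 44100 / 512)
  expect_lt(abs(hp$f2_hz - 1492), 44100 / 512)
  expect_lt(abs(hp$f3_hz - 2198), 44100 / 512)
  expect_equal(hp$f2f1_db, 35, tolerance = 1.5)
  expect_equal(hp$f2f3_db, 10, tolerance = 1.5)

  # equal maxima within a band resolve to the lower-frequency bin
  lv2 <- rep(-40, 257)
  i <- which(freqs >= 1100 & freqs <= 1800)
  lv2[i[3]] <- 0
  lv2[i[7]] <- 0
  spec2 <- new("CallSpectrum", freqsHz = freqs, levelsDb = lv2)
  expect_equal(harmonicPeaks(spec2)$f2_hz, freqs[i[3]])
  expect_error(harmonicPeaks(spec, bands = list(c(1, 2), c(3, 4), c(5, 6))),
               "no spectrum bins")
})

test_that("spectral cross-correlation is Pearson on linear amplitudes", {
  a <- specOfAmps(c(1, 5, 2, 8, 3))
  expect_equal(spectralCrossCorrelation(a, a), 1)
  # affine-rescaled amplitudes still correlate perfectly
  b <- specOfAmps(3 * c(1, 5, 2, 8, 3) + 2)
  expect_equal(spectralCrossCorrelation(a, b), 1, tolerance = 1e-12)
  # reversed ramp anticorrelates exactly
  expect_equal(
    spectralCrossCorrelation(specOfAmps(1:4), specOfAmps(4:1)), -1,
    tolerance = 1e-12)
  # symmetry
  c2 <- specOfAmps(c(2, 1, 9, 4, 4))
  expect_equal(spectralCrossCorrelation(a, c2),
               spectralCrossCorrelation(c2, a))
  expect_error(
    spectralCrossCorrelation(a, specOfAmps(c(1, 1, 1, 1, 1))), "constant")
  expect_error(
    spectralCrossCorrelation(a, specOfAmps(1:4)), "identical frequency grid")
})

test_that("band ratio reads the nearest bins to 1 and 2 kHz", {
  freqs <- (0:220) * 44100 / 440
  flat <- new("CallSpectrum", freqsHz = freqs, levelsDb = rep(0, 221))
  expect_equal(bandRatio(flat), 0)
  # the canonical 440-point grid lands on 1002.3 and 2004.5 Hz
  expect_equal(round(freqs[which.min(abs(freqs - 1000))], 1), 1002.3)
  expect_equal(round(freqs[which.min(abs(freqs - 2000))], 1), 2004.5)
  lv <- rep(-60, 221)
  lv[which.min(abs(freqs - 1000))] <- -5
  lv[which.min(abs(freqs - 2000))] <- -36
  planted <- new("CallSpectrum", freqsHz = freqs,
                 levelsDb = lv - max(lv))
  expect_equal(bandRatio(planted), 31)
  expect_error(bandRatio(flat, fHiHz = 30000), "Nyquist")
})

test_that("envelope blocks are non-overlapping block RMS values", {
  rec <- makeRec(sine(1000, 300))
  env <- callEnvelope(rec, list(begin_s = 0, end_s = 300 / 44100), 30L)
  expect_length(env, 10L)  # 300 samples / 30 per block
  # constant-amplitude sine whose period divides the block: constant RMS
  rec2 <- makeRec(sine(4410, 3000))
  env2 <- callEnvelope(rec2, wholeSel(rec2), 30L)
  inner <- env2[2:(length(env2) - 1)]
  expect_lt((max(inner) - min(inner)) / max(inner), 0.01)
  expect_equal(callEnvelope(makeRec(rep(0, 90)),
                            list(begin_s = 0, end_s = 90 / 44100)),
               rep(0, 3))
  expect_error(callEnvelope(rec, list(begin_s = 0, end_s = 10 / 44100)),
               "shorter than one envelope block")
})

test_that("modulation depth is 100(max - min)/max", {
  expect_equal(modulationDepth(rep(2, 10)), 0)
  expect_equal(modulationDepth(c(0, 1, 2)), 100)
  expect_equal(modulationDepth(c(1, 2, 1.5)), 50)
  expect_error(modulationDepth(numeric()), "empty")
  expect_error(modulationDepth(rep(0, 5)), "all-zero")
})

test_that("mid-third modulation depth reads the call's central segment", {
  # tone amplitude-modulated only in the middle third
  n <- 9000
  t <- (0:(n - 1)) / 44100
  mod <- rep(1, n)
  mid <- (n / 3):(2 * n / 3)
  mod[mid] <- 0.5 + 0.5 * abs(sin(2 * pi * 40 * t[mid]))
  rec <- makeRec(mod * sin(2 * pi * 1000 * t))
  md <- callModulationDepth(rec, wholeSel(rec))
  expect_gt(md, 30)
  expect_lt(md, 70)
})
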