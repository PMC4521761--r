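test_that("call SPL follows the gain + 20log10(RMS) convention", {
  rec <- makeRec(sine(1000, 44100))
  sel <- wholeSel(rec)
  # full-scale sine at gain G reads G + 20log10(1/sqrt(2))
  expect_equal(callSpl(rec, sel, 100), 100 + 20 * log10(1 / sqrt(2)),
               tolerance = 1e-6)
  # halving the amplitude drops SPL by 20log10(2) dB
  half <- makeRec(samples(rec) / 2)
  expect_equal(callSpl(rec, sel, 100) - callSpl(half, sel, 100),
               20 * log10(2), tolerance = 1e-9)
  expect_error(callSpl(makeRec(rep(0, 100)), list(begin_s = 0, end_s = 0.002),
                       100), "zero RMS")
})

test_that("call SPL is gain-equivariant", {
  rec <- makeRec(sine(700, 5000, amp = 0.2))
  sel <- wholeSel(rec)
  for (k in c(-12, 3, 9.5)) {
    boosted <- makeRec(samples(rec) * 10^(k / 20))
    expect_equal(callSpl(boosted, sel, 80), callSpl(rec, sel, 80) + k,
                 tolerance = 1e-9)
  }
})

test_that("power-subtraction noise correction matches its closed form", {
  # equal signal and noise powers: measured level is noise + 3.01 dB
  expect_equal(noiseCorrect(43.01, 40), 40, tolerance = 0.01)
  expect_equal(noiseCorrect(50, 40), 49.5424, tolerance = 1e-4)
  expect_error(noiseCorrect(40, 40), "must exceed")
  # correction strictly decreases the level and vanishes as SNR grows
  snrs <- c(1, 3.01, 6, 10, 20, 40)
  corr <- 40 + snrs - vapply(snrs, function(s) noiseCorrect(40 + s, 40), 0)
  expect_true(all(corr > 0))
  expect_true(all(diff(corr) < 0))
  expect_lt(corr[length(corr)], 1e-3)
  expect_equal(corr[2], 3.01, tolerance = 0.01)
})

test_that("spherical loss is 20log10(d/dref), about 6 dB per doubling", {
  expect_equal(sphericalLoss(0.25), 0)
  expect_equal(sphericalLoss(0.5), 20 * log10(2))
  expect_equal(round(sphericalLoss(0.5)), 6)
  expect_equal(sphericalLoss(8), 20 * log10(32), tolerance = 1e-12)
  expect_error(sphericalLoss(-1), "positive")
})

test_that("excess attenuation subtracts the spherical prediction", {
  # exactly spherical propagation gives EA = 0 at any distance
  for (d in c(0.5, 1, 2, 4, 8)) {
    expect_equal(excessAttenuation(75, 75 - sphericalLoss(d), d), 0,
                 tolerance = 1e-12)
  }
  expect_equal(excessAttenuation(75, 40, 8), 35 - 20 * log10(32),
               tolerance = 1e-6)
  # a far SPL above the spherical prediction means negative EA
  expect_equal(excessAttenuation(75, 75 - sphericalLoss(2) + 2, 2), -2,
               tolerance = 1e-12)
  expect_error(excessAttenuation(75, 70, 0.2), "exceed the reference")
})
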