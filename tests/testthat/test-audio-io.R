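test_that("WAV round trip preserves count, rate and values", {
  x <- sine(440, 4410)
  for (spec in list(list(bits = 16L, tol = 2^-15), list(bits = 24L, tol = 2^-22),
                    list(bits = 32L, tol = 1e-7))) {
    f <- withr::local_tempfile(fileext = ".wav")
    if (spec$bits == 32L) {
      writeWave(x, 44100, f, format = "float")
    } else {
      writeWave(x, 44100, f, bits = spec$bits)
    }
    rec <- readWave(f)
    expect_length(samples(rec), length(x))
    expect_equal(sampleRate(rec), 44100)
    expect_lt(max(abs(samples(rec) - x)), spec$tol * 1.01)
  }
})

test_that("16-bit full-scale PCM maps to sample units near 1", {
  f <- withr::local_tempfile(fileext = ".wav")
  writeWave(rep(c(1, -1), 100), 8000, f, bits = 16L)
  rec <- readWave(f)
  expect_equal(max(samples(rec)), 1, tolerance = 1e-4)
  expect_equal(min(samples(rec)), -1, tolerance = 1e-4)
})

test_that("channel selection is 0-based and bounds-checked", {
  f <- withr::local_tempfile(fileext = ".wav")
  left <- sine(300, 500)
  right <- sine(700, 500)
  writeWave(cbind(left, right), 44100, f, format = "float")
  expect_lt(max(abs(samples(readWave(f, channel = 0L)) - left)), 1e-6)
  expect_lt(max(abs(samples(readWave(f, channel = 1L)) - right)), 1e-6)
  expect_error(readWave(f, channel = 2L), "channel 2")
})

test_that("malformed WAV input fails naming the offending chunk", {
  f <- withr::local_tempfile(fileext = ".wav")
  writeBin(c(charToRaw("JUNKxxxxJUNK"), raw(64)), f)
  expect_error(readWave(f), "RIFF")
  f2 <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:10), f2)
  expect_error(readWave(f2), "too short")
  expect_error(readWave(file.path(tempdir(), "absent.wav")), "not found")
})

test_that("selection tables parse, sort, and validate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSelections(data.frame(begin_s = c(1.0, 0.10), end_s = c(1.25, 0.39)), f)
  sel <- readSelections(f)
  expect_equal(nrow(sel), 2L)
  expect_equal(sel$begin_s, c(0.10, 1.0))     # sorted by begin time
  expect_equal(sel$call_index, 1:2)

  # Raven-style header aliases
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Begin Time (s)\tEnd Time (s)", "0.5\t0.8"), f2)
  expect_equal(readSelections(f2)$end_s, 0.8)

  # empty table -> zero selections
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("begin_s\tend_s", f3)
  expect_equal(nrow(readSelections(f3)), 0L)

  expect_error(validateSelections(data.frame(begin_s = 0.5, end_s = 0.4)),
               "end_s <= begin_s")
  expect_error(
    validateSelections(data.frame(begin_s = c(0, 0.2), end_s = c(0.3, 0.5))),
    "overlap")
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "0\t1"), f4)
  expect_error(readSelections(f4), "begin_s")
})

test_that("calibration gain anchors the tone to its reference level", {
  expect_equal(calibrationGain(makeTone(rep(0.1, 1000))), 113.8)
  expect_equal(calibrationGain(makeTone(rep(1, 1000))), 93.8)
  # applying the gain to the tone itself recovers 93.8 dB SPL
  tone <- makeTone(sine(1000, 44100, amp = 0.35))
  g <- calibrationGain(tone)
  rec <- makeRec(samples(tone))
  expect_equal(callSpl(rec, wholeSel(rec), g), 93.8, tolerance = 1e-9)
  expect_error(calibrationGain(makeTone(rep(0, 100))), "silent")
})

test_that("calibration is invariant to a common sample-unit rescaling", {
  tone <- makeTone(sine(1000, 44100, amp = 0.2))
  call <- sine(800, 2000, amp = 0.03)
  splOf <- function(k) {
    g <- calibrationGain(makeTone(samples(tone) * k))
    rec <- makeRec(call * k)
    callSpl(rec, wholeSel(rec), g)
  }
  expect_equal(splOf(1), splOf(7.3), tolerance = 1e-10)
})
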