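## Minimal RIFF/WAVE I/O. Supports PCM 16/24-bit and IEEE float32, mono or
## multi-channel. Integer PCM is normalized by 2^(bits-1) so full scale maps
## to [-1, 1); the calibration tone makes the absolute scale irrelevant.

#' Read a WAV file
#'
#' Reads one channel of a RIFF/WAVE file (PCM 16-bit, PCM 24-bit or IEEE
#' float32). Integer PCM samples are scaled by `2^(bits-1)` to dimensionless
#' units in \[-1, 1); float data are returned as stored.
#'
#' @param path path to a `.wav` file.
#' @param channel 0-based channel index (default 0, the first channel).
#' @param distanceCm,individual,species,arrayId optional metadata attached to
#'   the returned object.
#' @return a [CalibratedRecording-class].
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWave(sin(2 * pi * 440 * (0:999) / 44100), 44100, f)
#' rec <- readWave(f)
#' sampleRate(rec)
#' @export
readWave <- function(path, channel = 0L, distanceCm = NA_real_,
                     individual = NA_character_, species = NA_character_,
                     arrayId = NA_integer_) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  w <- .readWavFile(path)
  nch <- ncol(w$data)
  if (channel < 0L || channel >= nch) {
    stop(sprintf("channel %d requested but file '%s' has %d channel(s)",
                 channel, path, nch))
  }
  new("CalibratedRecording",
      samples = w$data[, channel + 1L], sampleRate = w$sampleRate,
      distanceCm = distanceCm, individual = individual, species = species,
      arrayId = as.integer(arrayId), channel = as.integer(channel))
}

#' Read a WAV file as a calibration tone
#'
#' @param path path to the tone WAV.
#' @param referenceSplDb the tone's known level, dB SPL RMS. The canonical
#'   study calibrator emits 93.8 dB SPL RMS.
#' @param channel 0-based channel index.
#' @return a [CalibrationTone-class].
#' @export
readCalibrationTone <- function(path, referenceSplDb = 93.8, channel = 0L) {
  rec <- readWave(path, channel = channel)
  new("CalibrationTone", samples = rec@samples, sampleRate = rec@sampleRate,
      referenceSplDb = referenceSplDb)
}

#' Write a WAV file
#'
#' @param samples numeric vector (mono) or matrix with one column per channel;
#'   values outside \[-1, 1\] are clipped for integer PCM.
#' @param sampleRate sampling rate in Hz.
#' @param path output path.
#' @param bits 16 or 24 for integer PCM; ignored when `format = "float"`.
#' @param format `"pcm"` (default) or `"float"` (IEEE float32).
#' @return `path`, invisibly.
#' @export
writeWave <- function(samples, sampleRate, path, bits = 16L,
                      format = c("pcm", "float")) {
  format <- match.arg(format)
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  nch <- ncol(samples)
  n <- nrow(samples)
  interleaved <- as.numeric(t(samples))
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "float") {
    bits <- 32L
    fmtCode <- 3L
    body <- writeBin(interleaved, raw(), size = 4L, endian = "little")
  } else {
    if (!bits %in% c(16L, 24L)) stop("bits must be 16 or 24 for PCM")
    fmtCode <- 1L
    full <- 2^(bits - 1)
    x <- round(pmax(pmin(interleaved, 1 - 1 / full), -1) * full)
    if (bits == 16L) {
      body <- writeBin(as.integer(x), raw(), size = 2L, endian = "little")
    } else {
      x <- as.integer(x)
      neg <- x < 0
      u <- ifelse(neg, x + 2^24, x)
      b0 <- as.raw(u %% 256)
      b1 <- as.raw((u %/% 256) %% 256)
      b2 <- as.raw((u %/% 65536) %% 256)
      body <- as.raw(rbind(b0, b1, b2))
    }
  }
  blockAlign <- nch * bits / 8
  byteRate <- sampleRate * blockAlign
  dataSize <- length(body)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(as.integer(fmtCode), con, size = 2L, endian = "little")
  writeBin(as.integer(nch), con, size = 2L, endian = "little")
  writeBin(as.integer(sampleRate), con, size = 4L, endian = "little")
  writeBin(as.integer(byteRate), con, size = 4L, endian = "little")
  writeBin(as.integer(blockAlign), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4L, endian = "little")
  writeBin(body, con)
  invisible(path)
}

## Parse RIFF chunks; returns list(sampleRate, data = samples matrix).
.readWavFile <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 44L) stop("not a WAV file (too short): ", path)
  if (rawToChar(raw[1:4]) != "RIFF" || rawToChar(raw[9:12]) != "WAVE") {
    stop("not a RIFF/WAVE file (bad 'RIFF'/'WAVE' chunk): ", path)
  }
  pos <- 13L
  fmt <- NULL
  dataRaw <- NULL
  while (pos + 8L <= length(raw)) {
    id <- rawToChar(raw[pos:(pos + 3L)])
    size <- .leUint(raw[(pos + 4L):(pos + 7L)])
    start <- pos + 8L
    if (id == "fmt ") {
      f <- raw[start:(start + size - 1L)]
      fmt <- list(
        code = .leUint(f[1:2]),
        channels = .leUint(f[3:4]),
        sampleRate = .leUint(f[5:8]),
        bits = .leUint(f[15:16])
      )
    } else if (id == "data") {
      dataRaw <- raw[start:min(start + size - 1L, length(raw))]
    }
    pos <- start + size + (size %% 2L)  # chunks are word-aligned
  }
  if (is.null(fmt)) stop("WAV missing 'fmt ' chunk: ", path)
  if (is.null(dataRaw)) stop("WAV missing 'data' chunk: ", path)
  code <- fmt$code
  if (code == 65534L) code <- 1L  # WAVE_FORMAT_EXTENSIBLE, assume PCM
  if (code == 1L && fmt$bits == 16L) {
    x <- readBin(dataRaw, "integer", n = length(dataRaw) %/% 2L,
                 size = 2L, signed = TRUE, endian = "little") / 32768
  } else if (code == 1L && fmt$bits == 24L) {
    n3 <- length(dataRaw) %/% 3L
    m <- matrix(as.integer(dataRaw[seq_len(3L * n3)]), nrow = 3L)
    u <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    x <- ifelse(u >= 2^23, u - 2^24, u) / 2^23
  } else if (code == 3L && fmt$bits == 32L) {
    x <- readBin(dataRaw, "numeric", n = length(dataRaw) %/% 4L,
                 size = 4L, endian = "little")
  } else {
    stop(sprintf(
      "unsupported WAV encoding in 'fmt ' chunk (format code %d, %d-bit): %s",
      fmt$code, fmt$bits, path))
  }
  nch <- fmt$channels
  nFrames <- length(x) %/% nch
  list(sampleRate = fmt$sampleRate,
       data = matrix(x[seq_len(nFrames * nch)], ncol = nch, byrow = TRUE))
}

.leUint <- function(b) sum(as.numeric(b) * 256^(seq_along(b) - 1L))
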