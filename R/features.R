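## Feature extraction: turns calibrated recordings + selections into the
## long-format feature table the trend models consume. One row per
## (species, individual, array, distance, call).

#' Per-call acoustic features for one channel
#'
#' Computes every feature the propagation analysis uses for a single call on
#' a single channel: calibrated SPL (noise-corrected by power subtraction
#' when the signal-to-noise ratio is below `snrCutoffDb`), excess attenuation
#' against the reference-channel SPL, the single-frame spectrum with spectral
#' cross-correlation against the reference-channel spectrum, harmonic ratios
#' (harmonic calls) or the 1-2 kHz ratio and mid-third modulation depth
#' (pulsed calls), and call duration.
#'
#' @param rec a [CalibratedRecording-class] (with `distanceCm` set).
#' @param sel one selection (`begin_s`, `end_s`).
#' @param gain calibration gain, dB.
#' @param profile the `speciesProfile` (frame settings, bands, call kind).
#' @param refSpl SPL of the same call on the reference (25 cm) channel, dB;
#'   NA skips excess attenuation.
#' @param refSpectrum the reference channel's [CallSpectrum-class]; NULL skips
#'   cross-correlation.
#' @param noiseSplDb measured background-noise SPL for this channel, dB; NA
#'   skips noise correction.
#' @param snrCutoffDb apply noise correction only below this SNR (default 10).
#' @param refDistanceCm reference distance, cm.
#' @param ccOnDb correlate spectra on dB levels instead of linear amplitudes.
#' @return one-row data.frame of features.
#' @export
extractCallFeatures <- function(rec, sel, gain, profile,
                                refSpl = NA_real_, refSpectrum = NULL,
                                noiseSplDb = NA_real_, snrCutoffDb = 10,
                                refDistanceCm = 25, ccOnDb = FALSE) {
  spl <- callSpl(rec, sel, gain)
  snr <- if (is.finite(noiseSplDb)) spl - noiseSplDb else NA_real_
  corrected <- FALSE
  if (is.finite(snr) && snr < snrCutoffDb) {
    if (spl > noiseSplDb) {
      spl <- noiseCorrect(spl, noiseSplDb)
      corrected <- TRUE
    }
  }
  d <- rec@distanceCm
  ea <- if (is.finite(refSpl) && is.finite(d) && d > refDistanceCm) {
    excessAttenuation(refSpl, spl, d / 100, refDistanceCm / 100)
  } else NA_real_
  spec <- powerSpectrum(rec, sel, profile$atFraction, profile$nFft)
  cc <- if (!is.null(refSpectrum) && is.finite(d) && d > refDistanceCm) {
    spectralCrossCorrelation(refSpectrum, spec, onDb = ccOnDb)
  } else NA_real_
  f2f1 <- f2f3 <- r12k <- md <- NA_real_
  if (profile$callKind == "harmonic") {
    hp <- harmonicPeaks(spec, profile$bands)
    f2f1 <- hp$f2f1_db
    f2f3 <- hp$f2f3_db
  } else {
    r12k <- bandRatio(spec)
    md <- callModulationDepth(rec, sel)
  }
  data.frame(
    species = rec@species, individual = rec@individual,
    array_id = rec@arrayId, distance_cm = d,
    call_index = sel$call_index %||% NA_integer_,
    spl_db = spl, spl_corrected = corrected, snr_db = snr,
    ea_db = ea, cc = cc, f2f1_db = f2f1, f2f3_db = f2f3,
    r12k_db = r12k, md_pct = md,
    duration_ms = 1000 * (sel$end_s - sel$begin_s)
  )
}

#' Extract the feature table from a synthetic (or real) study tree
#'
#' Walks a study directory of the layout written by [generateStudy()]
#' (`tone.wav`, then `<species>/<individual>/array<k>/ch<j>.wav` +
#' `selections.tsv`), establishes the calibration gain from the tone, and
#' extracts features for every selected call on every channel. Background
#' noise per channel is measured as the RMS SPL of the leading gap before the
#' first call (when at least 50 ms long); noise correction is applied only
#' when a call's SNR falls below `snrCutoffDb`.
#'
#' @param studyDir study root directory.
#' @param profiles list of `speciesProfile`s keyed by their `species` labels
#'   matching the species directories.
#' @param arrays named list of per-array channel distances, cm (channel `j`
#'   is at `arrays[[k]][j + 1]`).
#' @param referenceSplDb the calibration tone's known level, dB SPL RMS.
#' @param snrCutoffDb SNR cutoff for noise correction, dB (default 10).
#' @param refDistanceCm reference distance, cm (default 25).
#' @param ccOnDb correlate spectra on dB levels (default FALSE).
#' @return the feature table: one row per (species, individual, array,
#'   distance, call).
#' @export
extractFeatures <- function(studyDir,
                            profiles = list(harmonicProfile(),
                                            pulsedProfile()),
                            arrays = studyArrays(),
                            referenceSplDb = 93.8,
                            snrCutoffDb = 10, refDistanceCm = 25,
                            ccOnDb = FALSE) {
  tonePath <- file.path(studyDir, "tone.wav")
  if (!file.exists(tonePath)) {
    stop("study has no calibration tone: ", tonePath)
  }
  gain <- calibrationGain(readCalibrationTone(tonePath, referenceSplDb))
  names(profiles) <- vapply(profiles, `[[`, "", "species")
  rows <- list()
  for (sp in intersect(names(profiles), list.dirs(studyDir, recursive = FALSE,
                                                  full.names = FALSE))) {
    profile <- profiles[[sp]]
    spDir <- file.path(studyDir, sp)
    for (indId in list.dirs(spDir, recursive = FALSE, full.names = FALSE)) {
      for (arrId in names(arrays)) {
        arrDir <- file.path(spDir, indId, paste0("array", arrId))
        if (!dir.exists(arrDir)) next
        sel <- readSelections(file.path(arrDir, "selections.tsv"))
        if (!nrow(sel)) next
        dists <- arrays[[arrId]]
        refCh <- match(refDistanceCm, dists) - 1L
        if (is.na(refCh)) stop("array ", arrId, " lacks the reference distance")
        recs <- lapply(seq_along(dists) - 1L, function(ch) {
          p <- file.path(arrDir, sprintf("ch%d.wav", ch))
          if (!file.exists(p)) stop("missing channel file: ", p)
          readWave(p, channel = 0L, distanceCm = dists[ch + 1L],
                   individual = indId, species = sp,
                   arrayId = as.integer(arrId))
        })
        noiseSpl <- vapply(recs, .leadingNoiseSpl, numeric(1),
                           firstBeginS = sel$begin_s[1], gain = gain)
        refFeats <- lapply(seq_len(nrow(sel)), function(k) {
          s <- sel[k, ]
          list(
            spl = callSpl(recs[[refCh + 1L]], s, gain),
            spec = powerSpectrum(recs[[refCh + 1L]], s,
                                 profile$atFraction, profile$nFft)
          )
        })
        for (ch in seq_along(dists) - 1L) {
          for (k in seq_len(nrow(sel))) {
            s <- sel[k, ]
            rows[[length(rows) + 1L]] <- extractCallFeatures(
              recs[[ch + 1L]], s, gain, profile,
              refSpl = refFeats[[k]]$spl,
              refSpectrum = refFeats[[k]]$spec,
              noiseSplDb = noiseSpl[ch + 1L],
              snrCutoffDb = snrCutoffDb,
              refDistanceCm = refDistanceCm, ccOnDb = ccOnDb
            )
          }
        }
      }
    }
  }
  if (!length(rows)) stop("no analyzable recordings found under ", studyDir)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Noise SPL from the gap before the first call; NA when too short or silent.
.leadingNoiseSpl <- function(rec, firstBeginS, gain) {
  endS <- max(0, firstBeginS - 0.01)
  if (endS < 0.05) return(NA_real_)
  x <- sliceSelection(rec, list(begin_s = 0, end_s = endS))
  r <- .rms(x)
  if (r <= 0) return(NA_real_)
  gain + 20 * log10(r)
}

#' Write a feature table to CSV
#' @param table feature table from [extractFeatures()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path CSV path.
#' @return data.frame.
#' @export
readFeatureTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
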