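#' Block-RMS amplitude envelope of a selected call
#'
#' Absolute-amplitude envelope: one value per consecutive non-overlapping
#' block of `binSamples` samples (30-point smoothing, 0% window overlap in the
#' canonical settings), each value the RMS of its block. A trailing partial
#' block is dropped.
#'
#' @param rec a [CalibratedRecording-class].
#' @param sel one selection (`begin_s`, `end_s`).
#' @param binSamples block length in samples (default 30).
#' @return numeric vector of envelope values.
#' @export
callEnvelope <- function(rec, sel, binSamples = 30L) {
  x <- sliceSelection(rec, sel)
  if (length(x) < binSamples) {
    stop("selection shorter than one envelope block")
  }
  nb <- length(x) %/% binSamples
  blocks <- matrix(x[seq_len(nb * binSamples)], nrow = binSamples)
  sqrt(colMeans(blocks^2))
}

#' Modulation depth of an envelope
#'
#' Percentage contrast between the maximum and minimum envelope values:
#' `100 * (max - min) / max`, bounded in \[0, 100\]. Applied to the envelope
#' of the middle third of a pulsed call, its decline with distance indexes
#' temporal degradation.
#'
#' @param env numeric envelope values (see [callEnvelope()]).
#' @return modulation depth, percent.
#' @export
modulationDepth <- function(env) {
  if (!length(env)) stop("empty envelope")
  if (max(env) <= 0) stop("all-zero envelope: modulation depth undefined")
  100 * (max(env) - min(env)) / max(env)
}

#' Modulation depth of the middle third of a call
#'
#' Convenience wrapper: restricts the selection to its middle third by
#' duration, computes the block-RMS envelope there, and returns its
#' modulation depth.
#'
#' @inheritParams callEnvelope
#' @return modulation depth, percent.
#' @export
callModulationDepth <- function(rec, sel, binSamples = 30L) {
  dur <- sel$end_s - sel$begin_s
  mid <- list(begin_s = sel$begin_s + dur / 3,
              end_s = sel$begin_s + 2 * dur / 3)
  modulationDepth(callEnvelope(rec, mid, binSamples))
}
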