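#' Read a call selection table
#'
#' Selection tables are tab-delimited with begin/end times in seconds,
#' 0-based from the start of the recording. Canonical headers are `begin_s`
#' and `end_s`; the Raven-style aliases `Begin Time (s)` / `End Time (s)` are
#' accepted. Rows are returned sorted by begin time; overlapping selections
#' are rejected, as each selection must delimit one analyzable call.
#'
#' @param path path to a TSV selection table.
#' @return a data.frame with columns `begin_s`, `end_s`, `call_index`
#'   (1-based, in begin-time order). Zero rows for an empty table.
#' @export
readSelections <- function(path) {
  if (!file.exists(path)) stop("selection table not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  norm <- tolower(gsub("[^a-z0-9]+", "", tolower(names(tab))))
  bi <- match(TRUE, norm %in% c("begins", "begintimes"))
  ei <- match(TRUE, norm %in% c("ends", "endtimes"))
  if (is.na(bi) || is.na(ei)) {
    stop("selection table must have 'begin_s'/'end_s' columns ",
         "(or Raven 'Begin Time (s)'/'End Time (s)'): ", path)
  }
  sel <- data.frame(begin_s = as.numeric(tab[[bi]]),
                    end_s = as.numeric(tab[[ei]]))
  validateSelections(sel)
}

#' Validate and order raw begin/end selections
#'
#' @param sel data.frame with numeric `begin_s`, `end_s`.
#' @return the selections sorted by `begin_s` with a `call_index` column.
#' @export
validateSelections <- function(sel) {
  if (nrow(sel) == 0L) {
    return(data.frame(begin_s = numeric(), end_s = numeric(),
                      call_index = integer()))
  }
  if (any(!is.finite(sel$begin_s)) || any(!is.finite(sel$end_s))) {
    stop("selection times must be finite numbers")
  }
  if (any(sel$begin_s < 0)) stop("selection begin times must be >= 0")
  bad <- which(sel$end_s <= sel$begin_s)
  if (length(bad)) {
    stop(sprintf("selection %d has end_s <= begin_s (%.4f <= %.4f)",
                 bad[1], sel$end_s[bad[1]], sel$begin_s[bad[1]]))
  }
  sel <- sel[order(sel$begin_s), , drop = FALSE]
  if (nrow(sel) > 1L &&
      any(sel$begin_s[-1L] < sel$end_s[-nrow(sel)])) {
    stop("selections overlap; each call selection must be disjoint")
  }
  sel$call_index <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' Write a selection table
#'
#' @param sel data.frame with `begin_s`, `end_s` (and optionally more columns).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSelections <- function(sel, path) {
  write.table(sel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
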