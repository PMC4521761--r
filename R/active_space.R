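#' Active-space (communication range) estimate from an amplitude trend
#'
#' Inverts a fitted exponential SPL-versus-distance trend
#' `SPL(d) = a + b*exp(-c*d)` against a receiver detection threshold `T`:
#' the range is `-(1/c) * log((T - a)/b)` when `a < T < SPL(refDistanceCm)`,
#' `Inf` when the curve never falls to threshold (`T <= a`), and 0 when the
#' signal is already at or below threshold at the reference distance. Ranges
#' that invert to less than the reference distance are clamped to 0 with a
#' warning, since extrapolation toward the source is undefined.
#'
#' @param model a [TrendModel-class] with family `"exponential"`, `b > 0`,
#'   `c > 0`.
#' @param thresholdDb detection threshold, dB SPL (e.g. ~58 dB SPL for the
#'   harmonic-call species' conspecific auditory threshold).
#' @param refDistanceCm nearest measured distance, cm (default 25).
#' @return an [ActiveSpaceEstimate-class].
#' @examples
#' m <- new("TrendModel", family = "exponential",
#'          fixed = c(a = 35.42, b = 40.25, c = 0.00336),
#'          sigmaU = 0, sigmaE = 1, logLik = 0, nObs = 0L, nGroups = 0L,
#'          response = "spl_db", fit = NULL)
#' rangeCm(estimateRange(m, 58))  # ~172 cm: communication limited below 2 m
#' @export
estimateRange <- function(model, thresholdDb, refDistanceCm = 25) {
  if (!is(model, "TrendModel") || model@family != "exponential") {
    stop("estimateRange requires an exponential TrendModel; for other ",
         "families use numeric inversion of the predicted curve")
  }
  a <- model@fixed[["a"]]
  b <- model@fixed[["b"]]
  cc <- model@fixed[["c"]]
  if (b <= 0 || cc <= 0) stop("exponential trend must have b > 0 and c > 0")
  r <- .invertExponential(a, b, cc, thresholdDb, refDistanceCm)
  new("ActiveSpaceEstimate", rangeCm = r, thresholdDb = thresholdDb,
      model = model)
}

.invertExponential <- function(a, b, cc, threshold, refDistanceCm) {
  splRef <- a + b * exp(-cc * refDistanceCm)
  if (threshold <= a) return(Inf)
  if (threshold >= splRef) return(0)
  r <- -log((threshold - a) / b) / cc
  if (r < refDistanceCm) {
    warning("estimated range falls inside the reference distance; clamped to 0")
    return(0)
  }
  r
}

#' Parametric-bootstrap interval for the active-space range
#'
#' Draws fixed-effect parameter vectors from the multivariate normal
#' approximation at the fit (mean = estimates, covariance = the model's
#' fixed-effect covariance), re-inverts each against the threshold, and
#' returns a percentile interval. Infinite ranges (draws whose asymptote
#' exceeds the threshold) are retained, so an interval endpoint may be `Inf`.
#'
#' @param model an exponential [TrendModel-class] whose `fit` slot carries a
#'   fitted model with a fixed-effect covariance (`nlme` or `nls`).
#' @param thresholdDb detection threshold, dB SPL.
#' @param nBoot number of bootstrap draws (must be >= 1).
#' @param seed integer seed.
#' @param level interval level (default 0.95).
#' @param refDistanceCm nearest measured distance, cm.
#' @return list with `lo`, `hi`, `draws` (the bootstrap ranges).
#' @export
rangeCi <- function(model, thresholdDb, nBoot, seed = 1, level = 0.95,
                    refDistanceCm = 25) {
  if (nBoot < 1L) stop("nBoot must be >= 1")
  if (!is(model, "TrendModel") || model@family != "exponential") {
    stop("rangeCi requires an exponential TrendModel")
  }
  if (is.null(model@fit)) {
    stop("model carries no underlying fit; parameter covariance unavailable")
  }
  V <- as.matrix(vcov(model@fit))[c("a", "b", "c"), c("a", "b", "c")]
  if (any(!is.finite(V))) stop("degenerate parameter covariance")
  mu <- model@fixed[c("a", "b", "c")]
  if (max(abs(V)) < .Machine$double.eps) {
    r <- .invertExponential(mu[["a"]], mu[["b"]], mu[["c"]], thresholdDb,
                            refDistanceCm)
    return(list(lo = r, hi = r, draws = rep(r, nBoot)))
  }
  ch <- tryCatch(chol(V), error = function(e) {
    stop("degenerate parameter covariance: ", conditionMessage(e))
  })
  .withSeed(seed, {
    z <- matrix(rnorm(3 * nBoot), ncol = 3) %*% ch
    draws <- vapply(seq_len(nBoot), function(i) {
      p <- mu + z[i, ]
      if (p[["b"]] <= 0 || p[["c"]] <= 0) return(NA_real_)
      suppressWarnings(
        .invertExponential(p[["a"]], p[["b"]], p[["c"]], thresholdDb,
                           refDistanceCm))
    }, numeric(1))
    draws <- draws[!is.na(draws)]
    qs <- quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE, type = 1)
    list(lo = qs[1], hi = qs[2], draws = draws)
  })
}
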