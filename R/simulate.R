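## Analytic feature simulation: draws feature values directly from a
## profile's trend equations with per-individual random intercepts and
## residual noise, bypassing waveform rendering. This is the fast generator
## used for trend-recovery and selection studies; the waveform generator
## (generateStudy) exercises the same trends end-to-end through audio.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
  }
  force(expr)
}

## Deterministic per-stream sub-seed from a study seed and counters.
.splitSeed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in idx) {
    h <- (h * 1103515245 + as.double(k) * 12345 + 1) %% 2147483647
  }
  as.integer(h)
}

#' Simulate a feature table from a profile trend
#'
#' Draws `value = trend(dist) + u_i + e` for each individual, distance and
#' call, with `u_i ~ N(0, sigmaU^2)` per individual and
#' `e ~ N(0, sigmaE^2)` per call: the random-intercept structure the mixed
#' models assume. Values of bounded features are left untruncated; the
#' canonical noise scales keep them in range.
#'
#' @param profile a `speciesProfile`.
#' @param feature trend name (see [trendValue()]).
#' @param nIndividuals number of individuals.
#' @param callsPerSubject calls per individual per distance (default 10).
#' @param distancesCm distances, cm. Defaults to the six-distance transect,
#'   dropping the 25 cm reference for features defined only relative to it
#'   (`ea`, `cc`).
#' @param sigmaU random-intercept SD (response units). `NULL` uses the
#'   trend's stored default.
#' @param sigmaE residual SD (response units). `NULL` uses the trend's stored
#'   default.
#' @param seed integer seed; the draw is reproducible given (seed, arguments).
#' @return data.frame with `species`, `individual`, `distance_cm`,
#'   `call_index`, `value`, `truth` (the noise-free trend value) and
#'   `intercept` (the individual's random intercept).
#' @export
simulateFeatureTable <- function(profile, feature, nIndividuals,
                                 callsPerSubject = 10,
                                 distancesCm = NULL,
                                 sigmaU = NULL, sigmaE = NULL, seed = NULL) {
  tr <- profile$trends[[feature]]
  if (is.null(sigmaU)) sigmaU <- tr$sigmaU %||% 2
  if (is.null(sigmaE)) sigmaE <- tr$sigmaE %||% 1
  if (is.null(distancesCm)) {
    distancesCm <- studyDistances()
    if (feature %in% c("ea", "cc")) distancesCm <- setdiff(distancesCm, 25)
  }
  stopifnot(nIndividuals >= 2, callsPerSubject >= 1)
  .withSeed(seed, {
    u <- rnorm(nIndividuals, 0, sigmaU)
    grid <- expand.grid(call_index = seq_len(callsPerSubject),
                        distance_cm = distancesCm,
                        individual = seq_len(nIndividuals))
    truth <- trendValue(profile, feature, grid$distance_cm)
    data.frame(
      species = profile$species,
      individual = sprintf("ind%02d", grid$individual),
      distance_cm = grid$distance_cm,
      call_index = grid$call_index,
      value = truth + u[grid$individual] +
        rnorm(nrow(grid), 0, sigmaE),
      truth = truth,
      intercept = u[grid$individual]
    )
  })
}
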