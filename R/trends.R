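## Mixed-effects distance modelling. Factor-distance models and polynomial /
## species-comparison models are fitted with lme4; the exponential
## random-intercept trend with nlme. All model selection uses likelihood
## ratio tests between ML fits; a supported factor model is refitted by REML
## before contrasts are read off it.

.lrt <- function(llFull, llNull, df) {
  chi2 <- max(0, 2 * (llFull - llNull))
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

.checkResponse <- function(table, response) {
  need <- c("individual", "distance_cm", response)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  }
  dat <- table[is.finite(table[[response]]), , drop = FALSE]
  dat$.y <- dat[[response]]
  dat
}

#' Factor-distance mixed model with a likelihood-ratio test
#'
#' Fits `response ~ distance (categorical) + (1 | individual)` by maximum
#' likelihood and tests the distance effect against the intercept-only
#' random-intercept model with a likelihood-ratio test. When distance is
#' supported at `alpha`, the model is refitted by restricted maximum
#' likelihood (REML) and the REML fit is returned for contrast estimation.
#'
#' @param table a feature table (long format; needs `individual`,
#'   `distance_cm`, optionally `array_id`).
#' @param response name of the feature column to model.
#' @param arrayId optional microphone array to subset to.
#' @param alpha significance level for the distance effect (default 0.05).
#' @param transform optional transformation applied to the response before
#'   fitting (`"identity"`, `"log"`, `"sqrt"`).
#' @return list with `model` (lmerMod; REML fit if the distance effect was
#'   supported, else the ML fit), `lrt` (`chi2`, `df`, `p`), `reml` flag,
#'   `distances`, and `transform`.
#' @export
fitFactorModel <- function(table, response, arrayId = NULL, alpha = 0.05,
                           transform = c("identity", "log", "sqrt")) {
  transform <- match.arg(transform)
  if (!is.null(arrayId)) {
    table <- table[table$array_id == arrayId, , drop = FALSE]
  }
  dat <- .checkResponse(table, response)
  dat$.y <- .applyTransform(dat$.y, transform)
  dists <- sort(unique(dat$distance_cm))
  if (length(dists) < 2L) stop("need at least two distances to model")
  if (length(unique(dat$individual)) < 2L) {
    stop("need at least two individuals for a random intercept")
  }
  dat$dist_f <- factor(dat$distance_cm, levels = dists)
  full <- lme4::lmer(.y ~ dist_f + (1 | individual), data = dat, REML = FALSE)
  null <- lme4::lmer(.y ~ 1 + (1 | individual), data = dat, REML = FALSE)
  lrt <- .lrt(as.numeric(logLik(full)), as.numeric(logLik(null)),
              df = length(dists) - 1L)
  supported <- lrt$p < alpha
  model <- if (supported) {
    lme4::lmer(.y ~ dist_f + (1 | individual), data = dat, REML = TRUE)
  } else {
    full
  }
  list(model = model, lrt = lrt, reml = supported, distances = dists,
       response = response, transform = transform)
}

#' A priori contrasts against the reference distance
#'
#' With treatment coding and the nearest distance as the reference level, each
#' non-reference fixed effect estimates the difference from the reference
#' distance. Wald confidence intervals are widened by Bonferroni correction
#' (per-contrast level `1 - alpha/k` for `k` contrasts); a contrast is
#' significant when zero falls outside its interval.
#'
#' @param fitted result of [fitFactorModel()].
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with `distance_cm`, `estimate`, `ci_lo`, `ci_hi`,
#'   `significant`.
#' @export
contrastsVsReference <- function(fitted, alpha = 0.05) {
  model <- fitted$model
  fe <- lme4::fixef(model)
  idx <- grep("^dist_f", names(fe))
  if (!length(idx)) stop("model has no distance contrasts (reference only)")
  k <- length(idx)
  se <- sqrt(diag(as.matrix(vcov(model)))[idx])
  crit <- qnorm(1 - alpha / (2 * k))
  est <- unname(fe[idx])
  data.frame(
    distance_cm = as.numeric(sub("^dist_f", "", names(fe)[idx])),
    estimate = est,
    ci_lo = est - crit * se,
    ci_hi = est + crit * se,
    significant = (est - crit * se) > 0 | (est + crit * se) < 0
  )
}

.applyTransform <- function(y, transform) {
  switch(transform, identity = y, log = log(y), sqrt = sqrt(y))
}

.polyTrendModel <- function(dat, family, response) {
  ## fit on distance in m to keep the quadratic design well scaled; report
  ## coefficients per cm (log-likelihood is invariant to predictor scaling)
  dat$.d <- dat$distance_cm / 100
  form <- switch(family,
    none = .y ~ 1 + (1 | individual),
    linear = .y ~ .d + (1 | individual),
    quadratic = .y ~ .d + I(.d^2) + (1 | individual)
  )
  fit <- lme4::lmer(form, data = dat, REML = FALSE)
  fe <- lme4::fixef(fit)
  fixed <- switch(family,
    none = c(a = unname(fe[1])),
    linear = c(a = unname(fe[1]), b = unname(fe[2]) / 100),
    quadratic = c(a = unname(fe[1]), b = unname(fe[2]) / 100,
                  c = unname(fe[3]) / 1e4)
  )
  vc <- lme4::VarCorr(fit)
  new("TrendModel", family = family, fixed = fixed,
      sigmaU = attr(vc$individual, "stddev")[[1]],
      sigmaE = attr(vc, "sc"),
      logLik = as.numeric(logLik(fit)),
      nObs = nrow(dat),
      nGroups = length(unique(dat$individual)),
      response = response, fit = fit)
}

#' Exponential random-intercept trend
#'
#' Fits `y = a + b*exp(-c*dist) + u_i + e` by maximum likelihood with a
#' per-individual random intercept on `a` (distance in cm). Starting values
#' follow the distance means: `a0` is their minimum, `b0` their range, and
#' `c0` comes from a log-linear regression of the excess over `a0`; `c` is
#' kept in (1e-6, 1). If the nonlinear mixed fit fails to converge, the model
#' falls back to a fixed-effects-only nonlinear fit (`sigmaU = 0`) with a
#' warning; if the decay amplitude is degenerate (`b ~ 0`), it falls back to
#' the intercept-only mixed model with a warning.
#'
#' @param table feature table.
#' @param response feature column name.
#' @return a [TrendModel-class] with family `"exponential"` (or `"none"` after
#'   a degenerate fallback).
#' @export
fitExponentialTrend <- function(table, response) {
  dat <- .checkResponse(table, response)
  dists <- sort(unique(dat$distance_cm))
  if (length(dists) < 4L) {
    stop("need at least four distinct distances to fit the exponential trend")
  }
  means <- tapply(dat$.y, dat$distance_cm, mean)
  mDist <- as.numeric(names(means))
  a0 <- min(means)
  b0 <- max(means) - min(means)
  if (b0 <= .Machine$double.eps^0.5 * max(1, abs(a0))) {
    warning("response shows no amplitude over distance (b ~ 0); ",
            "falling back to the intercept-only model")
    return(.polyTrendModel(dat, "none", response))
  }
  excess <- pmax(means - a0, b0 * 1e-3)
  c0 <- -unname(coef(lm(log(excess) ~ mDist))[2])
  c0 <- min(max(c0, 1e-5), 0.5)
  fit <- tryCatch(
    nlme::nlme(.y ~ a + b * exp(-c * distance_cm),
               fixed = a + b + c ~ 1, random = a ~ 1 | individual,
               data = dat, start = c(a = a0, b = b0, c = c0),
               method = "ML",
               control = nlme::nlmeControl(maxIter = 200, pnlsMaxIter = 20,
                                           msMaxIter = 200, returnObject = FALSE)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warning("nonlinear mixed fit did not converge (", conditionMessage(fit),
            "); falling back to a fixed-effects nonlinear fit (sigmaU = 0)")
    nfit <- tryCatch(
      stats::nls(.y ~ a + b * exp(-c * distance_cm), data = dat,
                 start = list(a = a0, b = b0, c = c0),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE)),
      error = function(e) e
    )
    if (inherits(nfit, "error")) {
      warning("nonlinear fixed-effects fit failed too (",
              conditionMessage(nfit),
              "); falling back to the intercept-only model")
      return(.polyTrendModel(dat, "none", response))
    }
    cf <- coef(nfit)
    n <- nrow(dat)
    rss <- sum(residuals(nfit)^2)
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    return(new("TrendModel", family = "exponential",
               fixed = c(a = unname(cf["a"]), b = unname(cf["b"]),
                         c = unname(cf["c"])),
               sigmaU = 0, sigmaE = sqrt(rss / n), logLik = ll,
               nObs = nrow(dat),
               nGroups = length(unique(dat$individual)),
               response = response, fit = nfit))
  }
  cf <- nlme::fixef(fit)
  if (cf[["c"]] <= 1e-6 || cf[["c"]] >= 1) {
    warning("exponential decay rate estimate at its bound (c = ",
            signif(cf[["c"]], 3), ")")
  }
  vc <- nlme::VarCorr(fit)
  new("TrendModel", family = "exponential",
      fixed = c(a = unname(cf["a"]), b = unname(cf["b"]),
                c = unname(cf["c"])),
      sigmaU = suppressWarnings(as.numeric(vc["a", "StdDev"])),
      sigmaE = fit$sigma,
      logLik = as.numeric(logLik(fit)),
      nObs = nrow(dat),
      nGroups = length(unique(dat$individual)),
      response = response, fit = fit)
}

#' Fit a chosen trend family
#'
#' Fits one family of the random-intercept trend ladder by maximum
#' likelihood without model selection — the refit step of parameter-recovery
#' studies where the generating family is known.
#'
#' @param table feature table.
#' @param response feature column name.
#' @param family `"none"`, `"linear"`, `"quadratic"` or `"exponential"`.
#' @return a [TrendModel-class].
#' @export
fitTrendFamily <- function(table, response,
                           family = c("linear", "quadratic", "exponential",
                                      "none")) {
  family <- match.arg(family)
  if (family == "exponential") {
    return(fitExponentialTrend(table, response))
  }
  .polyTrendModel(.checkResponse(table, response), family, response)
}

#' Select the distance-trend family for a feature
#'
#' Fits the random-intercept trend ladder by maximum likelihood — no change,
#' linear, quadratic (interior extremum) — testing each step against its
#' simpler parent with a likelihood-ratio test at `alpha`, and additionally
#' fits the exponential trend (tested against the no-change model, 2 df).
#' The most complex supported polynomial is retained; when the quadratic step
#' is supported, the exponential (same fixed-parameter count) replaces it if
#' its own test is significant and its log-likelihood is higher. A supported
#' quadratic whose vertex `-b/(2c)` lies inside the observed distance range is
#' flagged as an interior-extremum trend.
#'
#' @param table feature table pooling the six-distance transect.
#' @param response feature column name.
#' @param alpha LRT significance level (default 0.05).
#' @param transform optional response transformation.
#' @return list with `model` (the selected [TrendModel-class]), `lrts`
#'   (likelihood-ratio tests for the linear, quadratic and exponential steps)
#'   and `interior_extremum` flag.
#' @export
selectTrend <- function(table, response, alpha = 0.05,
                        transform = c("identity", "log", "sqrt")) {
  transform <- match.arg(transform)
  dat <- .checkResponse(table, response)
  dat$.y <- .applyTransform(dat$.y, transform)
  dat0 <- dat
  dat0[[response]] <- dat0$.y
  m0 <- .polyTrendModel(dat, "none", response)
  m1 <- .polyTrendModel(dat, "linear", response)
  m2 <- .polyTrendModel(dat, "quadratic", response)
  lrtLin <- .lrt(m1@logLik, m0@logLik, 1L)
  lrtQuad <- .lrt(m2@logLik, m1@logLik, 1L)
  mExp <- tryCatch(
    suppressWarnings(fitExponentialTrend(dat0, response)),
    error = function(e) NULL
  )
  lrtExp <- if (!is.null(mExp) && mExp@family == "exponential") {
    .lrt(mExp@logLik, m0@logLik, 2L)
  } else {
    list(chi2 = NA_real_, df = 2L, p = NA_real_)
  }
  expOk <- is.finite(lrtExp$p) && lrtExp$p < alpha
  model <- if (lrtQuad$p < alpha) {
    if (expOk && mExp@logLik > m2@logLik) mExp else m2
  } else if (lrtLin$p < alpha) {
    m1
  } else if (expOk) {
    mExp
  } else {
    m0
  }
  interior <- FALSE
  if (model@family == "quadratic" && model@fixed[["c"]] != 0) {
    vertex <- -model@fixed[["b"]] / (2 * model@fixed[["c"]])
    interior <- vertex > min(dat$distance_cm) && vertex < max(dat$distance_cm)
  }
  list(model = model,
       lrts = list(linear = lrtLin, quadratic = lrtQuad,
                   exponential = lrtExp),
       interior_extremum = interior)
}

#' Two-species mixed-model comparison
#'
#' Fits `response ~ species * distance (categorical) + (1 | individual)` by
#' maximum likelihood and evaluates, by sequential likelihood-ratio tests,
#' the species-by-distance interaction (full vs additive), the distance main
#' effect (additive vs species-only) and the species main effect (additive vs
#' distance-only).
#'
#' @param table feature table containing both species at shared distances.
#' @param response feature column name.
#' @return list of three LRTs (`species`, `distance`, `interaction`), each
#'   `list(chi2, df, p)`, plus the full ML fit as `model`.
#' @export
compareSpecies <- function(table, response) {
  dat <- .checkResponse(table, response)
  if (length(unique(dat$species)) != 2L) {
    stop("species comparison requires exactly two species in the table")
  }
  dat$dist_f <- factor(dat$distance_cm)
  dat$species <- factor(dat$species)
  nd <- nlevels(dat$dist_f)
  full <- lme4::lmer(.y ~ species * dist_f + (1 | individual),
                     data = dat, REML = FALSE)
  add <- lme4::lmer(.y ~ species + dist_f + (1 | individual),
                    data = dat, REML = FALSE)
  spOnly <- lme4::lmer(.y ~ species + (1 | individual),
                       data = dat, REML = FALSE)
  distOnly <- lme4::lmer(.y ~ dist_f + (1 | individual),
                         data = dat, REML = FALSE)
  list(
    interaction = .lrt(as.numeric(logLik(full)), as.numeric(logLik(add)),
                       df = nd - 1L),
    distance = .lrt(as.numeric(logLik(add)), as.numeric(logLik(spOnly)),
                    df = nd - 1L),
    species = .lrt(as.numeric(logLik(add)), as.numeric(logLik(distOnly)),
                   df = 1L),
    model = full
  )
}

#' Serialise a TrendModel to a JSON-ready list
#'
#' @param model a [TrendModel-class].
#' @return a plain list (family, coefficients, variance components,
#'   log-likelihood, sizes) suitable for `jsonlite::write_json`.
#' @export
trendModelReport <- function(model) {
  list(
    family = model@family,
    response = model@response,
    fixed = as.list(model@fixed),
    sigma_u = model@sigmaU,
    sigma_e = model@sigmaE,
    loglik = model@logLik,
    n_obs = model@nObs,
    n_groups = model@nGroups
  )
}
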