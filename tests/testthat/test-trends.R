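suppressMessages(library(lme4))

test_that("factor-distance model: no effect gives chi2 near 0, planted drop is detected", {
  pp <- pulsedProfile()
  # flat response: LRT statistic ~ 0, distance unsupported
  flat <- pulsedProfile()
  flat$trends$spl <- list(family = "none", a = 70, b = 0)
  tabFlat <- simulateFeatureTable(flat, "spl", 6, 4,
                                  distancesCm = c(25, 50, 100, 400),
                                  sigmaU = 1, sigmaE = 0.5, seed = 21)
  tabFlat$array_id <- 1L
  fmFlat <- suppressMessages(fitFactorModel(tabFlat, "value"))
  expect_lt(fmFlat$lrt$chi2, qchisq(0.95, 3))
  expect_false(fmFlat$reml)

  # planted ~20 dB drop across distances: overwhelming evidence
  tab <- simulateFeatureTable(pp, "spl", 8, 5,
                              distancesCm = c(25, 50, 100, 400),
                              sigmaU = 2, sigmaE = 1, seed = 22)
  tab$array_id <- 1L
  fm <- fitFactorModel(tab, "value")
  expect_equal(fm$lrt$df, 3L)
  expect_lt(fm$lrt$p, 1e-4)
  expect_true(fm$reml)
  expect_error(fitFactorModel(tab[tab$distance_cm == 25, ], "value"),
               "two distances")
})

test_that("balanced two-distance fixed effect equals the difference of distance means", {
  set.seed(33)
  d <- expand.grid(individual = sprintf("i%d", 1:6), distance_cm = c(25, 100),
                   call_index = 1:4)
  d$value <- 70 - 0.05 * d$distance_cm + rnorm(nrow(d))
  fm <- suppressMessages(fitFactorModel(d, "value"))
  means <- tapply(d$value, d$distance_cm, mean)
  est <- fixef(fm$model)[["dist_f100"]]
  expect_equal(est, unname(means["100"] - means["25"]), tolerance = 1e-6)
})

test_that("contrasts vs reference use Bonferroni-widened Wald intervals", {
  pp <- pulsedProfile()
  tab <- simulateFeatureTable(pp, "spl", 8, 5,
                              distancesCm = c(25, 50, 100, 400),
                              sigmaU = 2, sigmaE = 1, seed = 7)
  tab$array_id <- 1L
  fm <- fitFactorModel(tab, "value")
  ct <- contrastsVsReference(fm)
  expect_equal(nrow(ct), 3L)
  expect_true(all(ct$ci_lo <= ct$estimate & ct$estimate <= ct$ci_hi))
  expect_equal(ct$significant, ct$ci_lo > 0 | ct$ci_hi < 0)
  # k = 3: per-contrast coverage 1 - 0.05/3 (98.33%)
  se <- sqrt(diag(as.matrix(vcov(fm$model))))[2:4]
  expect_equal((ct$ci_hi - ct$ci_lo) / 2, qnorm(1 - 0.05 / 6) * se,
               tolerance = 1e-8, ignore_attr = TRUE)
  # all distances truly differ from the 25 cm reference here
  expect_true(all(ct$significant))
})

test_that("family-wise error of Bonferroni contrasts stays at alpha under the null", {
  nSim <- 200
  hits <- 0
  for (r in seq_len(nSim)) {
    set.seed(1000 + r)
    d <- expand.grid(individual = sprintf("i%d", 1:8),
                     distance_cm = c(25, 50, 100, 400), call_index = 1:3)
    u <- rnorm(8, 0, 1)
    d$value <- 60 + u[as.integer(factor(d$individual))] + rnorm(nrow(d))
    d$dist_f <- factor(d$distance_cm)
    fit <- suppressMessages(
      lme4::lmer(value ~ dist_f + (1 | individual), data = d, REML = TRUE))
    ct <- contrastsVsReference(list(model = fit))
    if (any(ct$significant)) hits <- hits + 1
  }
  fwer <- hits / nSim
  expect_lte(fwer, 0.05 + 2 * sqrt(0.05 * 0.95 / nSim))
})

test_that("exponential trend recovers noise-free parameters to 4 significant figures", {
  hp <- harmonicProfile()
  tab <- simulateFeatureTable(hp, "spl", 5, 2, sigmaU = 0, sigmaE = 1e-6,
                              seed = 11)
  m <- suppressWarnings(fitExponentialTrend(tab, "value"))
  expect_equal(m@family, "exponential")
  expect_equal(fixedCoefs(m)[["a"]], 35.42, tolerance = 1e-4)
  expect_equal(fixedCoefs(m)[["b"]], 40.25, tolerance = 1e-4)
  expect_equal(fixedCoefs(m)[["c"]], 0.00336, tolerance = 1e-4)
})

test_that("exponential trend recovers the pulsed-species parameters under noise", {
  pp <- pulsedProfile()
  tab <- simulateFeatureTable(pp, "spl", 17, 10, sigmaU = 2, sigmaE = 1,
                              seed = 12)
  m <- fitExponentialTrend(tab, "value")
  expect_equal(fixedCoefs(m)[["a"]], 47.39, tolerance = 0.08)
  expect_equal(fixedCoefs(m)[["b"]], 37.60, tolerance = 0.08)
  expect_equal(fixedCoefs(m)[["c"]], 0.00397, tolerance = 0.1)
  expect_equal(m@sigmaU, 2, tolerance = 0.5)
  expect_equal(m@sigmaE, 1, tolerance = 0.2)
  # flat response falls back to the intercept-only model with a warning
  flat <- tab
  flat$value <- 50 + rnorm(nrow(flat), 0, 1e-3)
  w <- capture_warnings(
    m0 <- suppressMessages(fitExponentialTrend(flat, "value")))
  expect_match(paste(w, collapse = " "), "falling back|b ~ 0")
  expect_equal(m0@family, "none")
  expect_error(fitExponentialTrend(tab[tab$distance_cm %in% c(25, 50), ],
                                   "value"), "four distinct distances")
})

test_that("trend selection finds the planted family per feature", {
  hp <- harmonicProfile()
  pp <- pulsedProfile()
  # linear CC decline, slope sign negative
  cc <- simulateFeatureTable(hp, "cc", 15, 10, sigmaU = 0.01, sigmaE = 0.02,
                             seed = 31)
  stCc <- suppressMessages(selectTrend(cc, "value"))
  expect_equal(trendFamily(stCc$model), "linear")
  expect_lt(fixedCoefs(stCc$model)[["b"]], 0)
  # exponential SPL decay
  spl <- simulateFeatureTable(hp, "spl", 15, 10, sigmaU = 2, sigmaE = 1,
                              seed = 32)
  stSpl <- suppressMessages(selectTrend(spl, "value"))
  expect_equal(trendFamily(stSpl$model), "exponential")
  # quadratic with an interior maximum
  quad <- simulateFeatureTable(pp, "r12k", 17, 10, sigmaU = 1, sigmaE = 1.5,
                               seed = 33)
  stQ <- suppressMessages(selectTrend(quad, "value"))
  expect_equal(trendFamily(stQ$model), "quadratic")
  expect_true(stQ$interior_extremum)
  # pure noise keeps the no-change model
  noise <- cc
  noise$value <- rnorm(nrow(noise))
  stN <- suppressMessages(selectTrend(noise, "value"))
  expect_equal(trendFamily(stN$model), "none")
})

test_that("nested log-likelihoods are ordered and LRT statistics nonnegative", {
  pp <- pulsedProfile()
  tab <- simulateFeatureTable(pp, "md", 10, 5, sigmaU = 1, sigmaE = 2,
                              seed = 44)
  st <- suppressMessages(selectTrend(tab, "value"))
  expect_gte(st$lrts$linear$chi2, 0)
  expect_gte(st$lrts$quadratic$chi2, 0)
  expect_true(all(vapply(st$lrts, function(l) is.na(l$p) ||
                           (l$p >= 0 && l$p <= 1), TRUE)))
})

test_that("species comparison separates offset, distance and interaction effects", {
  hp <- harmonicProfile()
  base <- simulateFeatureTable(hp, "f2f1", 10, 6, sigmaU = 1, sigmaE = 1.5,
                               seed = 55)
  other <- base
  other$species <- "other_sp"
  other$individual <- paste0("o_", other$individual)
  set.seed(56)
  other$value <- other$value + 10 + rnorm(nrow(other), 0, 1.5)
  cs <- suppressMessages(compareSpecies(rbind(base, other), "value"))
  expect_lt(cs$species$p, 1e-6)      # planted 10 dB offset
  expect_lt(cs$distance$p, 1e-6)     # planted common trend
  expect_gt(cs$interaction$p, 0.01)  # parallel trends
  expect_equal(cs$species$df, 1L)
  expect_equal(cs$distance$df, 5L)
  expect_equal(cs$interaction$df, 5L)

  # species-specific slopes make the interaction significant
  steep <- base
  steep$species <- "steep_sp"
  steep$individual <- paste0("s_", steep$individual)
  steep$value <- steep$value - 0.02 * steep$distance_cm
  cs2 <- suppressMessages(compareSpecies(rbind(base, steep), "value"))
  expect_lt(cs2$interaction$p, 1e-4)
  expect_error(compareSpecies(base, "value"), "two species")
})
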