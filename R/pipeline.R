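## Pipeline orchestration: synth -> extract -> fit-factor -> fit-trend ->
## compare-species -> active-space, driven by a single YAML config, writing
## a machine-readable run report.

.configSchema <- list(
  top = c("seed", "out_dir", "stages", "synth", "analysis"),
  synth = c("n_individuals", "calls_per_subject", "sigma_u", "sigma_e",
            "noise_spl_db", "sample_rate", "gap_s"),
  analysis = c("alpha", "snr_cutoff_db", "reference_distance_cm", "cc_on_db",
               "threshold_db", "transforms")
)

.allStages <- c("synth", "extract", "fit-factor", "fit-trend",
                "compare-species", "active-space")

#' Read and validate a pipeline run configuration
#'
#' The config is YAML with keys `seed`, `out_dir`, `stages` and optional
#' `synth` / `analysis` blocks. Unknown keys are rejected so typos fail
#' loudly. All analysis thresholds (significance level, SNR cutoff, reference
#' distance, detection threshold) live here, never in stage logic.
#'
#' @param path YAML file path, or a list already parsed.
#' @return a validated config list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  .rejectUnknown(cfg, .configSchema$top, "config")
  .rejectUnknown(cfg$synth, .configSchema$synth, "config$synth")
  .rejectUnknown(cfg$analysis, .configSchema$analysis, "config$analysis")
  if (is.null(cfg$out_dir)) stop("config requires 'out_dir'")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$stages <- cfg$stages %||% .allStages
  bad <- setdiff(cfg$stages, .allStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  syn <- cfg$synth %||% list()
  cfg$synth <- list(
    n_individuals = unlist(syn$n_individuals %||%
                             c(E_calcaratus = 15L, E_emiliopugini = 17L)),
    calls_per_subject = syn$calls_per_subject %||% 10L,
    sigma_u = syn$sigma_u %||% 2,
    sigma_e = syn$sigma_e %||% 1,
    noise_spl_db = syn$noise_spl_db %||% 36,
    sample_rate = syn$sample_rate %||% 44100,
    gap_s = syn$gap_s %||% 0.4
  )
  ana <- cfg$analysis %||% list()
  cfg$analysis <- list(
    alpha = ana$alpha %||% 0.05,
    snr_cutoff_db = ana$snr_cutoff_db %||% 10,
    reference_distance_cm = ana$reference_distance_cm %||% 25,
    cc_on_db = isTRUE(ana$cc_on_db),
    threshold_db = ana$threshold_db %||% 58,
    transforms = ana$transforms %||% list()
  )
  cfg
}

.rejectUnknown <- function(x, allowed, where) {
  if (is.null(x)) return(invisible())
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
}

.speciesFeatures <- function(profile) {
  if (profile$callKind == "harmonic") {
    c("spl_db", "ea_db", "cc", "f2f1_db", "f2f3_db")
  } else {
    c("spl_db", "ea_db", "cc", "r12k_db", "md_pct")
  }
}

#' Subset a feature table to the pooled continuous-distance transect
#'
#' All of microphone array 1 plus the complementary distances of array 2
#' (those array 2 adds beyond array 1), giving the six-distance transect for
#' the continuous trend models.
#'
#' @param table feature table with `array_id` and `distance_cm`.
#' @param arrays the array design (default [studyArrays()]).
#' @return the subset table.
#' @export
pooledTransect <- function(table, arrays = studyArrays()) {
  a1 <- arrays[[1]]
  comp <- setdiff(arrays[[2]], a1)
  table[table$array_id == 1 |
          (table$array_id == 2 & table$distance_cm %in% comp), ,
        drop = FALSE]
}

#' Run the propagation-analysis pipeline
#'
#' Executes the configured stages in order under `out_dir`: generates the
#' synthetic study, extracts the feature table, fits per-array factor-distance
#' models with reference contrasts, selects continuous-distance trends on the
#' pooled transect, compares species, and estimates active space from the
#' exponential SPL trends. Writes `features.csv`, `factor_models.json`,
#' `contrasts.csv`, `trend_models.json`, `species_comparison.json`,
#' `active_space.json` and `run_report.json`. Idempotent given the same
#' config and seed.
#'
#' @param config path to a YAML config or a config list (see
#'   [readRunConfig()]).
#' @return invisibly, the run report list.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  studyDir <- file.path(out, "study")
  profiles <- list(harmonicProfile(), pulsedProfile())
  names(profiles) <- vapply(profiles, `[[`, "", "species")
  profiles <- profiles[names(profiles) %in% names(cfg$synth$n_individuals)]
  report <- list(seed = cfg$seed, config = cfg,
                 package_version = as.character(packageVersion("sonotrend")),
                 stages = list())
  run <- function(stage, fn) {
    if (!stage %in% cfg$stages) return(invisible())
    message("[sonotrend] stage: ", stage)
    info <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[stage]] <<- info
  }
  features <- NULL
  run("synth", function() {
    truth <- generateStudy(
      studyDir, profiles = unname(profiles),
      nIndividuals = cfg$synth$n_individuals,
      callsPerSubject = cfg$synth$calls_per_subject,
      sigmaU = cfg$synth$sigma_u, sigmaE = cfg$synth$sigma_e,
      noiseSplDb = cfg$synth$noise_spl_db %||% NA_real_,
      sampleRate = cfg$synth$sample_rate, seed = cfg$seed,
      gapS = cfg$synth$gap_s
    )
    list(truth_rows = nrow(truth))
  })
  run("extract", function() {
    features <<- extractFeatures(
      studyDir, profiles = unname(profiles),
      snrCutoffDb = cfg$analysis$snr_cutoff_db,
      refDistanceCm = cfg$analysis$reference_distance_cm,
      ccOnDb = cfg$analysis$cc_on_db
    )
    writeFeatureTable(features, file.path(out, "features.csv"))
    list(feature_rows = nrow(features),
         distances = sort(unique(features$distance_cm)))
  })
  loadFeatures <- function() {
    if (is.null(features)) {
      features <<- readFeatureTable(file.path(out, "features.csv"))
    }
    features
  }
  run("fit-factor", function() {
    tab <- loadFeatures()
    models <- list()
    contrasts <- list()
    for (sp in names(profiles)) {
      spTab <- tab[tab$species == sp, , drop = FALSE]
      for (resp in .speciesFeatures(profiles[[sp]])) {
        for (arr in sort(unique(spTab$array_id))) {
          tr <- cfg$analysis$transforms[[resp]] %||% "identity"
          fm <- tryCatch(
            fitFactorModel(spTab, resp, arrayId = arr,
                           alpha = cfg$analysis$alpha, transform = tr),
            error = function(e) NULL
          )
          if (is.null(fm)) next
          key <- sprintf("%s.%s.array%s", sp, resp, arr)
          models[[key]] <- list(species = sp, response = resp,
                                array_id = arr, transform = tr,
                                lrt = fm$lrt, reml = fm$reml)
          if (fm$reml) {
            ct <- contrastsVsReference(fm, alpha = cfg$analysis$alpha)
            ct$species <- sp
            ct$response <- resp
            ct$array_id <- arr
            contrasts[[key]] <- ct
          }
        }
      }
    }
    jsonlite::write_json(models, file.path(out, "factor_models.json"),
                         auto_unbox = TRUE, digits = NA)
    if (length(contrasts)) {
      write.csv(do.call(rbind, contrasts), file.path(out, "contrasts.csv"),
                row.names = FALSE)
    }
    list(models = length(models), contrast_tables = length(contrasts))
  })
  trendFits <- list()
  run("fit-trend", function() {
    tab <- pooledTransect(loadFeatures())
    for (sp in names(profiles)) {
      spTab <- tab[tab$species == sp, , drop = FALSE]
      for (resp in .speciesFeatures(profiles[[sp]])) {
        tr <- cfg$analysis$transforms[[resp]] %||% "identity"
        fit <- tryCatch(
          selectTrend(spTab, resp, alpha = cfg$analysis$alpha,
                      transform = tr),
          error = function(e) NULL
        )
        if (is.null(fit)) next
        key <- sprintf("%s.%s", sp, resp)
        trendFits[[key]] <<- fit
      }
    }
    rep <- lapply(trendFits, function(fit) {
      c(trendModelReport(fit$model),
        list(lrts = fit$lrts, interior_extremum = fit$interior_extremum))
    })
    jsonlite::write_json(rep, file.path(out, "trend_models.json"),
                         auto_unbox = TRUE, digits = NA)
    list(models = length(trendFits),
         families = vapply(trendFits, function(f) f$model@family, ""))
  })
  run("compare-species", function() {
    if (length(profiles) < 2L) return(list(skipped = "one species only"))
    tab <- pooledTransect(loadFeatures())
    comp <- list()
    for (resp in c("spl_db", "ea_db", "cc")) {
      cs <- tryCatch(compareSpecies(tab, resp), error = function(e) NULL)
      if (is.null(cs)) next
      comp[[resp]] <- cs[c("species", "distance", "interaction")]
    }
    jsonlite::write_json(comp, file.path(out, "species_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    list(responses = names(comp))
  })
  run("active-space", function() {
    tab <- pooledTransect(loadFeatures())
    res <- list()
    for (sp in names(profiles)) {
      spTab <- tab[tab$species == sp, , drop = FALSE]
      fit <- trendFits[[sprintf("%s.spl_db", sp)]]
      model <- if (!is.null(fit) && fit$model@family == "exponential") {
        fit$model
      } else {
        tryCatch(fitExponentialTrend(spTab, "spl_db"),
                 error = function(e) NULL)
      }
      if (is.null(model) || model@family != "exponential") next
      est <- estimateRange(model, cfg$analysis$threshold_db,
                           cfg$analysis$reference_distance_cm)
      res[[sp]] <- list(range_cm = est@rangeCm,
                        threshold_db = est@thresholdDb,
                        model = trendModelReport(model))
    }
    jsonlite::write_json(res, file.path(out, "active_space.json"),
                         auto_unbox = TRUE, digits = NA)
    list(species = names(res))
  })
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
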