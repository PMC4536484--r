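## Study orchestration: synthesis or ingestion, the >5% occurrence filter,
## per-response delta/binomial modelling with per-part AICc selection,
## spatially corrected evaluation with the binomial-only fallback rule,
## and prediction + kriged-error mapping, all from one configuration.

#' Occurrence filter for modelled species
#'
#' Occurrence (%) is the share of hauls in which a species was caught:
#' `100 * #(density > 0) / #hauls`. Only species *strictly* above
#' `minOccurrencePct` are retained for modelling (a species at exactly the
#' threshold is excluded); the full occurrence table is returned for
#' reporting.
#'
#' @param survey survey table with `density_*` columns.
#' @param minOccurrencePct occurrence threshold in percent (default 5).
#' @return list: `retained` (character species ids), `occurrence`
#'   (data.frame: species, nPresent, occurrencePct, retained).
#' @export
filterSpecies <- function(survey, minOccurrencePct = 5) {
  stopifnot(nrow(survey) > 0, minOccurrencePct >= 0)
  densCols <- grep("^density_", names(survey), value = TRUE)
  species <- sub("^density_", "", densCols)
  nPresent <- vapply(densCols, function(cl) sum(survey[[cl]] > 0),
                     numeric(1))
  pct <- 100 * nPresent / nrow(survey)
  retained <- pct > minOccurrencePct
  list(retained = species[retained],
       occurrence = data.frame(species = species, nPresent = nPresent,
                               occurrencePct = pct, retained = retained,
                               row.names = NULL))
}

#' Build a study configuration
#'
#' Defaults reproduce the package's reference synthetic study: a 64x64
#' seascape at 866 m resolution, the six-species default assemblage, 120
#' stations per year over 8 survey years (960 hauls), the 5% occurrence
#' filter, all-subsets AICc selection over the five predictors, a 2/3-1/3
#' split and the 0.05 binomial-only significance rule.
#'
#' @param seed global seed; per-stage substreams are derived from it.
#' @param mode `"synthetic"` or `"csv"` (ingest `surveyCsv` +
#'   `environmentDir` of ASCII grids).
#' @param ... overrides for any default listed above (see the returned
#'   list's names).
#' @return list of class `studyConfig`.
#' @export
studyConfig <- function(seed = 1, mode = c("synthetic", "csv"), ...) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode, seed = as.integer(seed),
    grid = list(nRows = 64, nCols = 64, cellSize = 866),
    nYears = 8, nStations = 120, sweptArea = 0.06,
    species = NULL,                    # NULL = defaultSpeciesTruths()
    minOccurrencePct = 5,
    terms = predictorNames(),
    scheme = "all_subsets",
    splitRatio = 2 / 3,
    alpha = 0.05,
    vifThreshold = 2,
    modelRichness = TRUE,
    surveyCsv = NULL, environmentDir = NULL,
    outputDir = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "studyConfig"
  cfg
}

#' Read a study configuration from a YAML file
#'
#' Keys mirror [studyConfig()] arguments; unspecified keys keep defaults.
#'
#' @param path YAML file.
#' @return a `studyConfig`.
#' @export
readStudyConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(studyConfig, vals)
}

## deterministic per-stage substreams from the global seed (kept < 2^31)
stageSeed <- function(seed, stage) {
  offsets <- c(environment = 101L, survey = 211L, split = 307L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483587L
}

#' Run the full habitat-suitability study
#'
#' Executes the pipeline end to end: build (or read) the environment grid
#' and survey, apply the occurrence filter, VIF-screen the predictors once
#' per dataset, then for each retained species and (optionally) community
#' richness: split train/test, select terms per part by AICc, fit the
#' delta model, evaluate internally and externally, apply the
#' binomial-only fallback rule, and map predictions and kriged scaled
#' errors. Per-species failures are quarantined (recorded, pipeline
#' continues). The run is deterministic given the configuration.
#'
#' @param config a `studyConfig` (or list of overrides passed to
#'   [studyConfig()]).
#' @param outputDir optional output directory; when set, writes per-species
#'   selection and evaluation CSVs, prediction/error ASCII grids, the
#'   survey CSV, the occurrence table and a YAML run manifest.
#' @param verbose log progress to stderr.
#' @return (invisibly) list: `environment`, `survey`, `filter`, `vif`,
#'   `results` (per response: `selectionOccurrence`, `selectionPositive`,
#'   `fit`, `evaluation`, `prediction`, `errorRaster`, `mode`; or `failed`
#'   with the failure message for a quarantined response), `manifest`.
#' @export
runStudy <- function(config = studyConfig(), outputDir = config$outputDir,
                     verbose = TRUE) {
  if (!inherits(config, "studyConfig")) config <- do.call(studyConfig, config)
  log <- function(...) if (verbose) message("[deltahab] ", ...)
  if (config$mode == "synthetic") {
    log("generating environment (", config$grid$nRows, "x",
        config$grid$nCols, ")")
    env <- generateEnvironment(config$grid$nRows, config$grid$nCols,
                               config$grid$cellSize,
                               seed = stageSeed(config$seed, "environment"))
    truths <- if (is.null(config$species)) defaultSpeciesTruths()
              else config$species
    design <- surveyDesign(nStations = config$nStations,
                           sweptArea = config$sweptArea)
    log("simulating survey (", config$nYears, " years x ",
        config$nStations, " stations)")
    survey <- simulateSurvey(env, truths, design, nYears = config$nYears,
                             seed = stageSeed(config$seed, "survey"))
  } else {
    if (is.null(config$surveyCsv) || is.null(config$environmentDir))
      stop("csv mode requires 'surveyCsv' and 'environmentDir'",
           call. = FALSE)
    env <- readEnvironmentGrid(config$environmentDir)
    survey <- computeRichness(readSurveyCsv(config$surveyCsv))
  }
  filt <- filterSpecies(survey, config$minOccurrencePct)
  log("retained ", length(filt$retained), " species above ",
      config$minOccurrencePct, "% occurrence")
  vif <- vifScreen(survey, intersect(config$terms, names(survey)),
                   threshold = config$vifThreshold)
  if (!vif$pass)
    warning("predictor collinearity screen failed (VIF >= ",
            config$vifThreshold, ")", call. = FALSE)
  responses <- paste0("density_", filt$retained)
  if (isTRUE(config$modelRichness) && "richness" %in% names(survey))
    responses <- c(responses, "richness")
  results <- list()
  for (resp in responses) {
    log("modelling ", resp)
    results[[resp]] <- tryCatch(
      runOneResponse(resp, survey, env, config),
      error = function(e) {
        warning("response '", resp, "' quarantined: ",
                conditionMessage(e), call. = FALSE)
        list(failed = conditionMessage(e))
      })
  }
  manifest <- list(
    package = "deltahab",
    version = as.character(utils::packageVersion("deltahab")),
    seed = config$seed,
    config = unclass(config[setdiff(names(config), "species")]),
    nHauls = nrow(survey),
    retainedSpecies = filt$retained,
    trainRows = lapply(results, function(r)
      if (is.null(r$failed)) r$split$trainIdx else NULL),
    quarantined = names(results)[vapply(results, function(r)
      !is.null(r$failed), logical(1))])
  out <- list(environment = env, survey = survey, filter = filt, vif = vif,
              results = results, manifest = manifest)
  if (!is.null(outputDir)) writeStudyOutputs(out, outputDir)
  invisible(out)
}

runOneResponse <- function(resp, survey, env, config) {
  split <- splitTrainTest(survey, ratio = config$splitRatio,
                          seed = stageSeed(config$seed, "split"),
                          responses = resp)
  selOcc <- selectModel(split$train, resp, "occurrence",
                        terms = config$terms, scheme = config$scheme)
  selPos <- tryCatch(
    selectModel(split$train, resp, "positive", terms = config$terms,
                scheme = config$scheme),
    error = function(e) NULL)
  termsOcc <- selOcc@bestFit@terms
  fit <- if (is.null(selPos)) {
    fitHurdle(split$train, resp, termsOcc, mode = "binomial_only")
  } else {
    fitHurdle(split$train, resp, termsOcc, selPos@bestFit@terms)
  }
  evalRep <- evaluateModel(fit, split$train, split$test, resp,
                           alpha = config$alpha)
  if (evalRep$useBinomialOnly) {
    fit <- fitHurdle(split$train, resp, termsOcc, mode = "binomial_only")
    evalRep <- evaluateModel(fit, split$train, split$test, resp,
                             alpha = config$alpha)
  }
  pred <- predictRaster(fit, env)
  predTrain <- if (fit@mode == "delta")
    as.numeric(predictDelta(fit, split$train))
  else as.numeric(predictComponent(fit@occurrence, split$train))
  err <- errorSurface(split$train[, c("x", "y")], split$train[[resp]],
                      predTrain, env)
  list(split = split, selectionOccurrence = selOcc,
       selectionPositive = selPos, fit = fit, evaluation = evalRep,
       prediction = pred, errorRaster = err, mode = fit@mode)
}

writeStudyOutputs <- function(out, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  writeSurveyCsv(out$survey, file.path(outputDir, "survey.csv"))
  write.csv(out$filter$occurrence,
            file.path(outputDir, "occurrence_table.csv"), row.names = FALSE)
  write.csv(out$vif$table, file.path(outputDir, "vif.csv"),
            row.names = FALSE)
  writeEnvironmentGrid(out$environment, file.path(outputDir, "environment"))
  for (resp in names(out$results)) {
    r <- out$results[[resp]]
    if (!is.null(r$failed)) next
    safe <- gsub("[^A-Za-z0-9_]", "_", resp)
    writeSelectionCsv(r$selectionOccurrence,
                      file.path(outputDir,
                                paste0(safe, "_selection_occurrence.csv")))
    if (!is.null(r$selectionPositive))
      writeSelectionCsv(r$selectionPositive,
                        file.path(outputDir,
                                  paste0(safe, "_selection_positive.csv")))
    writeEvaluationCsv(r$evaluation,
                       file.path(outputDir, paste0(safe, "_evaluation.csv")))
    writeAsciiGrid(r$prediction,
                   file.path(outputDir, paste0(safe, "_prediction.asc")))
    writeAsciiGrid(r$errorRaster,
                   file.path(outputDir, paste0(safe, "_error.asc")))
  }
  yaml::write_yaml(out$manifest, file.path(outputDir, "manifest.yaml"))
  invisible(outputDir)
}
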