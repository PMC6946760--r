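# Config-driven pipeline commands tying the stages together:
# pre-processing -> segmentation -> feature extraction -> dimensionality
# reduction -> classification.  Each command is a pure function of
# (config, seed, inputs); a manifest written next to every artifact records
# the configuration and seed for reproducibility.  The thin command-line
# front end in `inst/scripts/emgmpr.R` maps sub-commands onto these
# functions.

#' Read a pipeline run configuration
#'
#' Configurations are YAML or JSON mappings; recognised keys (all optional
#' unless noted): `preset` (`"easy"`/`"hard"`) or `input`/`schedule` paths,
#' `subjects` (number of synthetic subjects), `reps`, `features` (block
#' vector or set name, default `"FS"`), `classifier` (default `"MLE"`),
#' `folds`, `seed`, `pca` (components, 0 = off), `filter`, `thresholds`,
#' `bands` (parameter mappings passed to [filterConfig()],
#' [thresholdConfig()], [bandConfig()]), `outputDir`.
#'
#' @param path YAML or JSON file.
#' @param overrides named list merged over the file values.
#' @return A `runConfig` list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list()
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  defaults <- list(preset = NULL, input = NULL, schedule = NULL,
                   subjects = 1L, reps = 3L, features = "FS",
                   classifier = "MLE", folds = 10L, seed = 1L, pca = 0L,
                   filter = list(), thresholds = list(), bands = list(),
                   outputDir = "emgmpr-out", applyFilter = TRUE)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!is.null(cfg$preset) && !is.null(cfg$input))
    stop("config must name exactly one input source (preset or input)")
  structure(cfg, class = "runConfig")
}

runConfigObjects <- function(cfg) {
  list(filter = do.call(filterConfig, cfg$filter),
       thresholds = do.call(thresholdConfig, cfg$thresholds),
       bands = do.call(bandConfig, cfg$bands))
}

writeManifest <- function(cfg, dir, artifact) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(artifact = artifact,
                   config = unclass(cfg),
                   package = "emgmpr",
                   version = as.character(utils::packageVersion("emgmpr")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, paste0(artifact, ".manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

loadSessions <- function(cfg) {
  if (!is.null(cfg$preset)) {
    presetFun <- switch(tolower(cfg$preset), easy = easyPreset,
                        hard = hardPreset,
                        stop("unknown preset: ", cfg$preset))
    recs <- lapply(seq_len(cfg$subjects), function(i)
      generateSession(presetFun(seed = cfg$seed + i - 1L, reps = cfg$reps),
                      subjectId = sprintf("synthetic%02d", i)))
    names(recs) <- vapply(recs, subjectId, "")
    recs
  } else if (!is.null(cfg$input)) {
    rec <- readRecording(cfg$input, schedulePath = cfg$schedule)
    setNames(list(rec), subjectId(rec))
  } else stop("config must provide a preset or an input recording")
}

sessionFeatures <- function(rec, cfg, objs) {
  rec <- if (isTRUE(cfg$applyFilter)) filterRecording(rec, objs$filter) else rec
  ws <- segmentWindows(trimContractions(rec))
  assembleFeatures(ws, cfg$features, cfg = objs$thresholds, bands = objs$bands)
}

#' Pipeline commands
#'
#' `runSimulate` writes synthetic session CSVs (+ schedule sidecars);
#' `runExtract` writes one feature CSV per session; `runEvaluate`
#' cross-validates the configured classifier and writes the JSON/CSV report;
#' `runSelect` performs forward-selection/backward-elimination over the
#' configured candidate blocks and writes the selected set as JSON.
#'
#' @param cfg a `runConfig` from [readRunConfig()].
#' @return The main artifact (invisibly for writers): `runEvaluate` returns
#'   the `EMGEvaluation`, `runSelect` the selection list.
#' @export
runSimulate <- function(cfg) {
  recs <- loadSessions(cfg)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(recs))
    writeRecording(recs[[nm]], file.path(cfg$outputDir, paste0(nm, ".csv")))
  writeManifest(cfg, cfg$outputDir, "simulate")
  invisible(names(recs))
}

#' @rdname runSimulate
#' @export
runExtract <- function(cfg) {
  objs <- runConfigObjects(cfg)
  recs <- loadSessions(cfg)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(recs)) {
    fm <- sessionFeatures(recs[[nm]], cfg, objs)
    writeFeatureMatrix(fm, file.path(cfg$outputDir, paste0(nm, ".features.csv")))
  }
  writeManifest(cfg, cfg$outputDir, "extract")
  invisible(names(recs))
}

#' @rdname runSimulate
#' @export
runEvaluate <- function(cfg) {
  objs <- runConfigObjects(cfg)
  recs <- loadSessions(cfg)
  fms <- lapply(recs, sessionFeatures, cfg = cfg, objs = objs)
  if (cfg$pca > 0L)
    fms <- lapply(fms, function(fm) pcaApply(pcaFit(fm, cfg$pca), fm))
  ev <- crossValidate(fms, cfg$classifier, folds = cfg$folds, seed = cfg$seed,
                      config = classifierConfig(seed = cfg$seed))
  writeReport(ev, cfg$outputDir)
  writeManifest(cfg, cfg$outputDir, "evaluate")
  ev
}

#' @rdname runSimulate
#' @export
runSelect <- function(cfg) {
  objs <- runConfigObjects(cfg)
  recs <- loadSessions(cfg)
  candidates <- if (length(cfg$features) == 1L) featureSet(cfg$features)
                else cfg$features
  wss <- lapply(recs, function(rec) {
    r <- if (isTRUE(cfg$applyFilter)) filterRecording(rec, objs$filter) else rec
    segmentWindows(trimContractions(r))
  })
  nClasses <- length(unique(unlist(lapply(wss, windowLabels))))
  evaluator <- function(blocks) {
    fms <- lapply(wss, assembleFeatures, blocks = blocks,
                  cfg = objs$thresholds, bands = objs$bands)
    ev <- crossValidate(fms, cfg$classifier, folds = cfg$folds,
                        seed = cfg$seed,
                        config = classifierConfig(seed = cfg$seed))
    ev@meanRecall
  }
  sel <- forwardBackwardSelect(candidates, evaluator, nClasses = nClasses)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(blocks = sel$blocks, accuracy = sel$accuracy),
                       file.path(cfg$outputDir, "selected_features.json"),
                       auto_unbox = TRUE, digits = NA)
  writeManifest(cfg, cfg$outputDir, "select")
  sel
}
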