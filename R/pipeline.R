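## End-to-end wiring: simulate -> train/evaluate (four configurations) ->
## report. The exported functions are the interface; inst/cli/hsinerve.R is
## a thin command-line wrapper over them.

#' Load a run configuration
#'
#' YAML (or JSON) file with optional keys: `scene` (arguments to
#' [sceneConfig()]), `subjects`, `window`, `epochs`, `batchSize`,
#' `learningRate`, `configurations`, `seed`. Missing keys take package
#' defaults; `overrides` (a named list) wins over the file.
#'
#' @param path config file path, or NULL for all defaults.
#' @param overrides named list of overrides.
#' @return validated run-config list.
#' @export
loadRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- list(scene = list(), subjects = 8L, window = 5L, epochs = 12L,
              batchSize = 32L, learningRate = 0.001,
              configurations = modelConfigurations(), seed = 1L)
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
    fileCfg <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, fileCfg)
  }
  cfg <- modifyList(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Simulate a cohort and write it to disk
#'
#' Generates the configured cohort and writes each subject in the package's
#' exchange formats (ENVI cube + PNG/JSON mask), plus a `manifest.json`
#' listing subjects, paths, seeds and md5 checksums. Deterministic: the same
#' config and seed give identical checksums.
#'
#' @param config run config from [loadRunConfig()] (or NULL for defaults).
#' @param outDir output directory.
#' @return the manifest, invisibly.
#' @export
cmdSimulate <- function(config = NULL, outDir) {
  if (is.null(config) || !length(config)) config <- loadRunConfig()
  scene <- do.call(sceneConfig, modifyList(config$scene, list(seed = config$seed)))
  cohort <- makeCohort(scene, config$subjects)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cohort, function(subject) {
    paths <- writeSubject(subject, outDir)
    list(subjectId = subject$subjectId,
         files = as.list(paths),
         md5 = as.list(tools::md5sum(unname(paths))))
  })
  manifest <- list(seed = config$seed, subjects = length(cohort),
                   height = scene$height, width = scene$width,
                   bands = scene$bands, entries = entries)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a simulated cohort back from disk
#'
#' @param dir directory written by [cmdSimulate()].
#' @return list of subjects (`cube`, `mask`, `subjectId`).
#' @export
readCohort <- function(dir) {
  manifestPath <- file.path(dir, "manifest.json")
  if (!file.exists(manifestPath)) stop(sprintf("no manifest.json in '%s'", dir))
  manifest <- jsonlite::fromJSON(manifestPath, simplifyVector = FALSE)
  lapply(manifest$entries, function(e) {
    cube <- readCube(e$files$cube)
    mask <- readMask(e$files$mask)
    list(cube = cube, mask = mask, subjectId = e$subjectId)
  })
}

#' Run the full study pipeline
#'
#' Simulates (or loads) a cohort, runs leave-one-patient-out
#' cross-validation for every requested model configuration (CNN, CNN+SNV,
#' SVM, SVM+SNV by default) and renders the comparison report. Identical
#' config and seed give a byte-identical metrics bundle.
#'
#' @param config run config from [loadRunConfig()] (or NULL for defaults).
#' @param outDir report output directory.
#' @param cohort optional pre-built cohort (skips simulation).
#' @param verbose print fold progress.
#' @return named list of [CVReport-class] objects, invisibly.
#' @export
runPipeline <- function(config = NULL, outDir = NULL, cohort = NULL,
                        verbose = FALSE) {
  if (is.null(config) || !length(config)) config <- loadRunConfig()
  if (is.null(cohort)) {
    scene <- do.call(sceneConfig, modifyList(config$scene, list(seed = config$seed)))
    cohort <- makeCohort(scene, config$subjects)
  }
  reports <- lapply(config$configurations, function(cc)
    runCV(cohort, cc, window = config$window, epochs = config$epochs,
          batchSize = config$batchSize, learningRate = config$learningRate,
          seed = config$seed, verbose = verbose))
  names(reports) <- toupper(config$configurations)
  if (!is.null(outDir)) renderReport(reports, outDir)
  invisible(reports)
}
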