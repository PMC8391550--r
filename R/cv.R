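## LOPOCV driver: per fold, all preprocessing (SNV flag, band scaler, class
## weights) is fitted on the training subjects only, the model is trained,
## and the held-out subject's annotated pixels are predicted.

#' Model configurations of the study
#'
#' The four combinations compared: CNN and SVM, each with and without SNV
#' normalization.
#'
#' @return character vector of configuration names.
#' @export
modelConfigurations <- function() c("CNN", "CNN+SNV", "SVM", "SVM+SNV")

parseConfiguration <- function(configuration) {
  parts <- strsplit(toupper(configuration), "+", fixed = TRUE)[[1L]]
  kind <- tolower(parts[1L])
  if (!kind %in% c("cnn", "svm"))
    stop(sprintf("unknown model kind '%s'", parts[1L]))
  normalization <- if (length(parts) > 1L && parts[2L] == "SNV") "snv" else "none"
  list(kind = kind, normalization = normalization)
}

#' Run leave-one-patient-out cross-validation for one configuration
#'
#' For each fold: the sub-volume dataset of the training subjects is built
#' with the configuration's normalization, class weights (CNN) or the band
#' scaler (SVM) are fitted on training data only, the model is trained, and
#' the held-out subject's annotated pixels are scored. Fully seeded and
#' deterministic.
#'
#' @param cohort list of subjects (each `list(cube, mask, subjectId)`).
#' @param configuration one of [modelConfigurations()] (case-insensitive).
#' @param window spatial window (default 5).
#' @param epochs,batchSize,learningRate CNN training budget.
#' @param seed global seed for the run.
#' @param verbose print per-fold progress.
#' @return a [CVReport-class].
#' @export
runCV <- function(cohort, configuration = "CNN", window = 5L, epochs = 12L,
                  batchSize = 32L, learningRate = 0.001, seed = 1L,
                  verbose = FALSE) {
  cfg <- parseConfiguration(configuration)
  ids <- vapply(cohort, function(s) s$subjectId, character(1))
  folds <- lopocvSplit(ids)
  cls <- cohort[[1L]]$mask@classSet
  K <- length(cls@codes)

  # one dataset for the whole cohort; folds are row subsets by subject, so
  # SNV (a per-pixel transform) is computed once and no fold-level statistic
  # leaks: the band scaler and class weights are fitted per fold below
  allData <- buildDataset(cohort, window, cfg$normalization)

  foldResults <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    trainData <- subsetDataset(allData, allData@subjects %in% fold$train)
    counts <- classCounts(trainData)
    if (any(counts == 0L))
      stop(sprintf("fold '%s': class(es) %s absent from the training subjects",
                   fold$test, paste(names(counts)[counts == 0L], collapse = ", ")))

    foldSeed <- as.integer((as.numeric(seed) * 131071 + fi * 524287) %% 2147483647)
    model <- if (cfg$kind == "cnn") {
      m <- buildCNN(window, length(trainData@wavelengths), cls,
                    cfg$normalization, seed = foldSeed)
      trainCNN(m, trainData, epochs = epochs, batchSize = batchSize,
               learningRate = learningRate, seed = foldSeed)
    } else {
      trainSVM(trainData, seed = foldSeed)
    }
    stopifnot(!fold$test %in% model@trainSubjects)    # leakage guard

    testData <- subsetDataset(allData, allData@subjects == fold$test)
    scores <- predictScores(model, testData)
    predicted <- classifyScores(scores, cls)
    truth <- testData@labels

    cm <- confusionMatrix(truth, predicted, cls)
    perClass <- t(vapply(cls@codes, function(code)
      oneVsAllMetrics(truth, predicted, code), numeric(3)))
    rownames(perClass) <- cls@labels

    foldResults[[fi]] <- list(subject = fold$test, truth = truth,
                              predicted = predicted, scores = scores,
                              confusion = cm, perClass = perClass)
    if (verbose)
      message(sprintf("[%s] fold %d/%d (test %s): macro sensitivity %.3f",
                      configuration, fi, length(folds), fold$test,
                      macroAverage(perClass[, "sensitivity"])))
  }

  # pooled confusion over all test pixels
  allTruth <- unlist(lapply(foldResults, `[[`, "truth"))
  allPred <- unlist(lapply(foldResults, `[[`, "predicted"))
  pooled <- confusionMatrix(allTruth, allPred, cls)

  # fold x class metric matrices
  perClass <- lapply(c(sensitivity = "sensitivity", specificity = "specificity",
                       dsc = "dsc"), function(metric)
    t(vapply(foldResults, function(fr) fr$perClass[, metric], numeric(K))))

  summarize <- function(mat, metric) {
    data.frame(metric = metric, class = cls@labels,
               mean = colMeans(mat, na.rm = TRUE),
               sd = apply(mat, 2L, sd, na.rm = TRUE),
               se = apply(mat, 2L, function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))),
               nFolds = colSums(!is.na(mat)), row.names = NULL)
  }
  summary <- do.call(rbind, Map(summarize, perClass, names(perClass)))

  # pooled per-class ROC over all folds' test pixels
  allScores <- do.call(rbind, lapply(foldResults, `[[`, "scores"))
  roc <- lapply(seq_len(K), function(k)
    rocCurve(allTruth == cls@codes[k], allScores[, k]))
  names(roc) <- cls@labels

  new("CVReport", configuration = toupper(configuration), folds = foldResults,
      pooledConfusion = pooled, perClass = perClass, summary = summary,
      roc = roc, seed = as.integer(seed))
}

#' CVReport accessors
#'
#' @param report a [CVReport-class].
#' @param metric one of "sensitivity", "specificity", "dsc".
#' @return `foldMetric`: folds x classes matrix; `metricSummary`: the
#'   per-class summary data.frame; `pooledConfusion`: the pooled confusion
#'   list; `rocData`: the per-class pooled ROC list.
#' @export
foldMetric <- function(report, metric = c("sensitivity", "specificity", "dsc")) {
  report@perClass[[match.arg(metric)]]
}

#' @rdname foldMetric
#' @export
metricSummary <- function(report) report@summary

#' @rdname foldMetric
#' @export
pooledConfusion <- function(report) report@pooledConfusion

#' @rdname foldMetric
#' @export
rocData <- function(report) report@roc

#' Pairwise model comparison with paired t-tests
#'
#' Per class and metric, a two-tailed paired t-test across folds between
#' every pair of configurations, with significance stars at p < 0.05 (*)
#' and p < 0.01 (**). p-values are reported to 4 decimals without
#' multiple-testing correction.
#'
#' @param reports named list of [CVReport-class] objects (same cohort).
#' @param metric which per-class metric to compare.
#' @return data.frame: modelA, modelB, class, t, df, p, stars.
#' @export
compareModels <- function(reports, metric = c("sensitivity", "specificity", "dsc")) {
  metric <- match.arg(metric)
  nm <- names(reports)
  if (is.null(nm)) nm <- vapply(reports, function(r) r@configuration, character(1))
  out <- list()
  cls <- colnames(reports[[1L]]@perClass[[metric]])
  for (i in seq_along(reports)) for (j in seq_along(reports)) {
    if (j <= i) next
    A <- reports[[i]]@perClass[[metric]]; B <- reports[[j]]@perClass[[metric]]
    for (cl in cls) {
      tt <- pairedTTest(A[, cl], B[, cl])
      out[[length(out) + 1L]] <- data.frame(
        modelA = nm[i], modelB = nm[j], class = cl, metric = metric,
        t = tt$t, df = tt$df, p = if (tt$degenerate) NA_real_ else round(tt$p, 4L),
        stars = if (tt$degenerate || is.na(tt$p)) ""
                else if (tt$p < 0.01) "**" else if (tt$p < 0.05) "*" else "")
    }
  }
  do.call(rbind, out)
}
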