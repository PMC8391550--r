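#' Train the RBF-kernel SVM baseline
#'
#' Fits a multi-class support vector machine (radial basis kernel, C = 1,
#' one-vs-one scheme) on per-wavelength features, after per-band
#' auto-scaling fitted on the training features only. The fitted scaler is
#' stored inside the model, so inference cannot bypass it.
#'
#' @param dataset a [SubVolumeDataset-class] (training fold only).
#' @param cost regularization parameter C (default 1).
#' @param gamma RBF kernel width; default `1 / (B * var(features))`, the
#'   scale-normalized library default.
#' @param seed seed (libsvm training itself is deterministic; kept for
#'   interface symmetry).
#' @return an [SVMModel-class].
#' @export
trainSVM <- function(dataset, cost = 1, gamma = NULL, seed = 1L) {
  stopifnot(is(dataset, "SubVolumeDataset"))
  if (length(unique(dataset@labels)) < 2L)
    stop("SVM training needs at least two classes")
  feats <- svmFeatures(dataset)
  scaler <- fitBandScaler(feats)
  X <- applyBandScaler(scaler, feats)
  if (is.null(gamma)) {
    v <- var(as.vector(X))
    gamma <- 1 / (ncol(X) * if (v > 0) v else 1)
  }
  cls <- dataset@classSet
  y <- droplevels(factor(dataset@labels, levels = cls@codes))
  set.seed(seed)
  fit <- e1071::svm(X, y, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  new("SVMModel", classSet = cls, normalization = dataset@normalization,
      trainSubjects = unique(dataset@subjects), fit = fit, scaler = scaler)
}

## one-vs-one decision values -> per-class scores: each class gets the sum
## of signed pairwise decision values cast in its favor. Comparable across
## pixels; monotone with the voting rule on clear margins.
ovoClassScores <- function(decisionValues, codes) {
  K <- length(codes)
  scores <- matrix(0, nrow(decisionValues), K,
                   dimnames = list(NULL, as.character(codes)))
  pairNames <- colnames(decisionValues)
  for (j in seq_along(pairNames)) {
    pair <- strsplit(pairNames[j], "/", fixed = TRUE)[[1L]]
    a <- match(pair[1L], as.character(codes))
    b <- match(pair[2L], as.character(codes))
    scores[, a] <- scores[, a] + decisionValues[, j]
    scores[, b] <- scores[, b] - decisionValues[, j]
  }
  scores
}

#' Per-class predictive scores
#'
#' Returns one score per class and sample; higher means more likely. For
#' the CNN the scores are the output-layer activations (logits); for the
#' SVM they are aggregated one-vs-one decision values. The model's
#' preprocessing provenance is enforced: a dataset whose `normalization`
#' tag differs from the model's is rejected.
#'
#' @param model a trained [ClassifierModel-class].
#' @param dataset a [SubVolumeDataset-class] (labels may be arbitrary; only
#'   the volumes are used), or a single w x w x B array for `normalization`
#'   mismatch checking the array is trusted to match.
#' @return numeric matrix n x K with class labels as column names.
#' @export
predictScores <- function(model, dataset) {
  cls <- model@classSet
  if (is(dataset, "SubVolumeDataset")) {
    if (dataset@normalization != model@normalization)
      stop(sprintf("model was trained with '%s' normalization but input carries '%s'",
                   model@normalization, dataset@normalization))
    vols <- dataset@volumes
    window <- dataset@window; B <- length(dataset@wavelengths)
  } else {
    d <- dim(dataset)
    vols <- matrix(flattenSubVolume(dataset), nrow = 1L)
    window <- d[1L]; B <- d[3L]
  }
  if (is(model, "CNNModel")) {
    if (!model@trained) stop("model is untrained")
    if (window != model@arch$window || B != model@arch$bands)
      stop(sprintf("input is %d x %d x %d but the model expects %d x %d x %d",
                   window, window, B, model@arch$window, model@arch$window,
                   model@arch$bands))
    scores <- matrix(0, nrow(vols), length(cls@codes))
    chunk <- 2048L
    for (start in seq(1L, nrow(vols), by = chunk)) {
      idx <- start:min(start + chunk - 1L, nrow(vols))
      scores[idx, ] <- t(.cnnForwardCpp(model@arch$layers, model@params,
                                        t(vols[idx, , drop = FALSE])))
    }
  } else {
    feats <- if (is(dataset, "SubVolumeDataset")) svmFeatures(dataset)
             else matrix(svmFeatures(dataset), nrow = 1L)
    X <- applyBandScaler(model@scaler, feats)
    pred <- predict(model@fit, X, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    trainedCodes <- as.integer(model@fit$levels)
    sub <- ovoClassScores(dv, trainedCodes)
    if (any(!is.finite(sub))) stop("non-finite predictive scores")
    # classes absent from training can never win a one-vs-one vote
    scores <- matrix(min(sub) - 1, nrow(sub), length(cls@codes))
    scores[, match(trainedCodes, cls@codes)] <- sub
  }
  if (any(!is.finite(scores))) stop("non-finite predictive scores")
  colnames(scores) <- cls@labels
  scores
}

#' Assign classes from scores
#'
#' Argmax over per-class scores; exact ties break toward the lowest class
#' code. NaN scores are an error.
#'
#' @param scores numeric matrix n x K (or a length-K vector).
#' @param classSet class set supplying the codes.
#' @return integer class codes, length n.
#' @export
classifyScores <- function(scores, classSet = tissueClasses()) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  if (any(is.nan(scores))) stop("NaN score")
  classSet@codes[max.col(scores, ties.method = "first")]
}

#' Per-pixel prediction over a cube
#'
#' Runs the model at the requested pixels (default: all annotated pixels of
#' the supplied mask; `pixels = "all"` predicts densely at every pixel) and
#' returns a label map plus per-class score planes. The model's
#' normalization is applied internally to the raw cube.
#'
#' @param model trained [ClassifierModel-class].
#' @param cube raw (unnormalized) [HSICube-class].
#' @param mask optional [AnnotationMask-class] restricting prediction to
#'   annotated pixels.
#' @param pixels optional n x 2 matrix of (row, col), or "all" for dense
#'   prediction.
#' @param window spatial window (default 5).
#' @return list: `labels` (H x W integer map, 0 where not predicted),
#'   `scores` (n x K matrix), `pixels` (n x 2 coordinates used).
#' @export
predictImage <- function(model, cube, mask = NULL, pixels = NULL, window = 5L) {
  stopifnot(is(cube, "HSICube"))
  d <- dim(cube@data)
  if (identical(pixels, "all")) {
    pixels <- as.matrix(expand.grid(row = seq_len(d[1L]), col = seq_len(d[2L])))
  } else if (is.null(pixels)) {
    if (is.null(mask)) stop("supply a mask or an explicit pixel list")
    px <- annotatedPixels(mask)
    pixels <- cbind(px$row, px$col)
  } else {
    pixels <- as.matrix(pixels)
  }
  if (nrow(pixels) && (any(pixels[, 1L] < 1L) || any(pixels[, 1L] > d[1L]) ||
                       any(pixels[, 2L] < 1L) || any(pixels[, 2L] > d[2L])))
    stop("pixel outside cube")
  proc <- if (model@normalization == "snv") snvNormalizeCube(cube) else cube
  B <- d[3L]
  vols <- matrix(0, nrow(pixels), window * window * B)
  for (i in seq_len(nrow(pixels)))
    vols[i, ] <- flattenSubVolume(extractSubVolume(proc, pixels[i, ], window))
  ds <- new("SubVolumeDataset", volumes = vols,
            labels = rep(1L, nrow(pixels)), subjects = rep(cube@subjectId, nrow(pixels)),
            centers = pixels, window = as.integer(window),
            wavelengths = cube@wavelengths, normalization = model@normalization,
            classSet = model@classSet)
  scores <- predictScores(model, ds)
  codes <- classifyScores(scores, model@classSet)
  labels <- matrix(0L, d[1L], d[2L])
  labels[pixels] <- codes
  list(labels = labels, scores = scores, pixels = pixels)
}
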