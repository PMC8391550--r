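#' Leave-one-patient-out cross-validation folds
#'
#' One fold per subject: fold i trains on every other subject and tests on
#' subject i, so a model is never trained and tested on the same subject.
#'
#' @param subjectIds character vector of distinct subject identifiers (>= 2).
#' @return list of folds, each `list(train = ids, test = id)`.
#' @export
lopocvSplit <- function(subjectIds) {
  if (length(subjectIds) < 2L) stop("LOPOCV needs at least 2 subjects")
  if (anyDuplicated(subjectIds)) stop("duplicate subject ids")
  lapply(subjectIds, function(id)
    list(train = setdiff(subjectIds, id), test = id))
}

#' Confusion matrix with row normalization
#'
#' Counts of (true class i, predicted class j) plus the row-normalized form
#' whose entry (i, j) is the proportion of class-i pixels predicted as j.
#' The diagonal of the normalized form equals per-class sensitivity. Rows
#' with zero support are flagged (NA), never divided.
#'
#' @param truth,predicted equal-length integer class-code vectors.
#' @param classSet class set fixing row/column order.
#' @return list: `counts` (K x K), `normalized` (K x K, rows sum to 1 where
#'   supported), `zeroSupport` (labels of classes absent from `truth`).
#' @export
confusionMatrix <- function(truth, predicted, classSet = tissueClasses()) {
  if (length(truth) != length(predicted) || !length(truth))
    stop("truth and predicted must be nonempty and of equal length")
  bad <- setdiff(unique(c(truth, predicted)), classSet@codes)
  if (length(bad))
    stop(sprintf("label(s) outside the class set: %s", paste(sort(bad), collapse = ", ")))
  f <- function(x) factor(x, levels = classSet@codes, labels = classSet@labels)
  counts <- table(truth = f(truth), predicted = f(predicted))
  counts <- matrix(as.integer(counts), nrow(counts), dimnames = dimnames(counts))
  support <- rowSums(counts)
  normalized <- counts / ifelse(support > 0L, support, NA_real_)
  list(counts = counts, normalized = normalized,
       zeroSupport = rownames(counts)[support == 0L])
}

#' One-vs-all sensitivity, specificity and Dice coefficient
#'
#' For class c against the union of all others:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' DSC = 2TP/(2TP+FP+FN) (the harmonic mean of precision and sensitivity,
#' i.e. the F1 score). Zero support for c leaves sensitivity and DSC NA
#' (flagged missing), never 0.
#'
#' @param truth,predicted integer class-code vectors.
#' @param code the class code evaluated.
#' @return named numeric: sensitivity, specificity, dsc.
#' @export
oneVsAllMetrics <- function(truth, predicted, code) {
  tp <- sum(truth == code & predicted == code)
  fn <- sum(truth == code & predicted != code)
  fp <- sum(truth != code & predicted == code)
  tn <- sum(truth != code & predicted != code)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  dsc <- if (2L * tp + fp + fn > 0L) 2 * tp / (2 * tp + fp + fn) else NA_real_
  c(sensitivity = sens, specificity = spec, dsc = dsc)
}

#' Macro average of a per-class metric
#'
#' Unweighted mean over classes with defined (non-NA) values; classes with
#' undefined values are excluded, not zeroed.
#'
#' @param values per-class metric values (may contain NA).
#' @return scalar mean.
#' @export
macroAverage <- function(values) {
  if (all(is.na(values))) stop("no class has a defined metric value")
  mean(values, na.rm = TRUE)
}

#' ROC curve and AUC for one class
#'
#' Sweeps the detection threshold over all distinct scores, producing a
#' stepwise (FPR, TPR) curve from (0, 0) to (1, 1), with AUC by the
#' trapezoidal rule. Ties in score are handled so that the AUC equals the
#' probability that a random positive outscores a random negative, ties
#' counted one half.
#'
#' @param labels logical (or 0/1) vector: TRUE for the positive class.
#' @param scores numeric scores, higher = more positive.
#' @return list: `fpr`, `tpr`, `thresholds` (decreasing), `auc`.
#' @export
rocCurve <- function(labels, scores) {
  labels <- as.logical(labels)
  nP <- sum(labels); nN <- sum(!labels)
  if (nP == 0L || nN == 0L)
    stop("ROC needs both positive and negative samples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # collapse tied scores into single threshold steps
  lastOfRun <- c(s[-1L] != s[-length(s)], TRUE)
  cumTP <- cumsum(l)[lastOfRun]
  cumFP <- cumsum(!l)[lastOfRun]
  tpr <- c(0, cumTP / nP)
  fpr <- c(0, cumFP / nN)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[lastOfRun]), auc = auc)
}

#' Two-tailed paired t-test
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on the paired differences, df = n - 1,
#' two-tailed p from the t distribution. Zero difference variance is
#' degenerate: no p is reported.
#'
#' @param a,b equal-length paired metric vectors (e.g. one value per fold).
#' @return list: `t`, `df`, `p`, `degenerate`.
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  s <- sd(d)
  if (s == 0)
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, degenerate = TRUE))
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = n - 1L, p = 2 * pt(-abs(tstat), df = n - 1L),
       degenerate = FALSE)
}

#' Error map of a prediction
#'
#' RGB image that is black wherever the prediction agrees with the
#' annotation or the pixel is unlabeled, and shows the display color of the
#' incorrectly predicted class elsewhere.
#'
#' @param mask ground-truth [AnnotationMask-class].
#' @param predictedLabels H x W integer map of predicted codes.
#' @return numeric array H x W x 3 in [0, 1].
#' @export
errorMap <- function(mask, predictedLabels) {
  truth <- mask@labels
  if (!all(dim(truth) == dim(predictedLabels)))
    stop("mask and prediction dimensions differ")
  cls <- mask@classSet
  H <- nrow(truth); W <- ncol(truth)
  img <- array(0, dim = c(H, W, 3L))
  wrong <- truth != 0L & predictedLabels != truth & predictedLabels != 0L
  if (any(wrong)) {
    idx <- which(wrong)
    rgb <- grDevices::col2rgb(cls@colors[match(predictedLabels[idx], cls@codes)]) / 255
    img[idx] <- rgb[1L, ]
    img[idx + H * W] <- rgb[2L, ]
    img[idx + 2L * H * W] <- rgb[3L, ]
  }
  img
}
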