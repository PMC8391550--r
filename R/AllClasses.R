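#' @import methods
#' @importFrom stats rnorm runif sd var predict pt setNames
#' @importFrom utils write.csv modifyList
#' @importFrom Rcpp sourceCpp
#' @useDynLib hsinerve, .registration = TRUE
NULL

#' Tissue class set
#'
#' Ordered set of the seven recognizable classes. Code 0 is reserved for
#' unlabeled pixels and is never a class. Codes are fixed in alphabetical
#' order (artery = 1 ... vein = 7) so that confusion matrices and reports are
#' ordered identically across runs.
#'
#' @slot labels character vector of class names, in code order.
#' @slot codes integer codes 1..K.
#' @slot colors display color per class (hex), used for error maps.
#' @exportClass TissueClassSet
setClass("TissueClassSet",
  representation(labels = "character", codes = "integer", colors = "character"))

setValidity("TissueClassSet", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@codes) ||
      length(object@labels) != length(object@colors))
    msg <- c(msg, "labels, codes and colors must have equal length")
  if (anyDuplicated(object@codes)) msg <- c(msg, "codes must be unique")
  if (any(object@codes == 0L)) msg <- c(msg, "code 0 is reserved for unlabeled pixels")
  if (length(msg)) msg else TRUE
})

#' Hyperspectral cube
#'
#' An H x W x B volume of relative absorption values with a band-center
#' wavelength axis. The band axis is last; spatial coordinates are (row, col).
#'
#' @slot data numeric array H x W x B, all finite.
#' @slot wavelengths strictly increasing, equally spaced band centers in nm.
#' @slot subjectId identifier of the imaged subject.
#' @exportClass HSICube
setClass("HSICube",
  representation(data = "array", wavelengths = "numeric", subjectId = "character"))

setValidity("HSICube", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-dimensional array")
  else if (d[3L] != length(object@wavelengths))
    msg <- c(msg, sprintf("band axis (%d) does not match wavelength count (%d)",
                          d[3L], length(object@wavelengths)))
  if (!all(is.finite(object@data))) msg <- c(msg, "cube contains non-finite values")
  wl <- object@wavelengths
  if (length(wl) >= 2L) {
    dw <- diff(wl)
    if (any(dw <= 0)) msg <- c(msg, "wavelengths must be strictly increasing")
    else if (max(dw) - min(dw) > 1e-6 * mean(dw))
      msg <- c(msg, "wavelengths must be equally spaced")
  }
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Sparse per-pixel annotation mask
#'
#' Integer label map paired with a cube: 0 = unlabeled, codes 1..K per the
#' class set. Annotations cover only pixels whose class is certain, so most
#' of the map is 0.
#'
#' @slot labels integer matrix H x W with values in {0, codes}.
#' @slot classSet the [TissueClassSet-class] the codes refer to.
#' @exportClass AnnotationMask
setClass("AnnotationMask",
  representation(labels = "matrix", classSet = "TissueClassSet"))

setValidity("AnnotationMask", function(object) {
  msg <- character()
  vals <- unique(as.vector(object@labels))
  bad <- setdiff(vals, c(0L, object@classSet@codes))
  if (length(bad))
    msg <- c(msg, sprintf("mask contains codes outside the class set: %s",
                          paste(sort(bad), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Dataset of labeled sub-volumes
#'
#' One w x w x B sub-volume per annotated pixel, flattened row-wise for
#' efficient batched linear algebra. The flattening order is fixed:
#' band varies fastest, then window column, then window row (see
#' [extractSubVolume()]).
#'
#' @slot volumes numeric matrix N x (w*w*B), one flattened sub-volume per row.
#' @slot labels integer class codes, all nonzero.
#' @slot subjects subject identifier per sample.
#' @slot centers integer matrix N x 2 of (row, col) centers, 1-based.
#' @slot window odd spatial window side w.
#' @slot wavelengths band centers (length B).
#' @slot normalization "none" or "snv"; provenance of spectral preprocessing.
#' @slot classSet the class set.
#' @exportClass SubVolumeDataset
setClass("SubVolumeDataset",
  representation(volumes = "matrix", labels = "integer", subjects = "character",
                 centers = "matrix", window = "integer", wavelengths = "numeric",
                 normalization = "character", classSet = "TissueClassSet"))

setValidity("SubVolumeDataset", function(object) {
  msg <- character()
  n <- nrow(object@volumes)
  if (length(object@labels) != n || length(object@subjects) != n || nrow(object@centers) != n)
    msg <- c(msg, "volumes, labels, subjects and centers must agree in length")
  if (any(object@labels == 0L)) msg <- c(msg, "dataset labels must be nonzero class codes")
  w <- object@window; B <- length(object@wavelengths)
  if (ncol(object@volumes) != w * w * B)
    msg <- c(msg, "volume width does not match window^2 * bands")
  if (!object@normalization %in% c("none", "snv"))
    msg <- c(msg, "normalization must be 'none' or 'snv'")
  if (length(msg)) msg else TRUE
})

#' Per-band standardization (auto-scaling) parameters
#'
#' Mean and standard deviation per spectral band, fitted on training data
#' only and applied to held-out data unchanged.
#'
#' @slot mean per-band mean, length B.
#' @slot sd per-band standard deviation, all > 0.
#' @exportClass BandScaler
setClass("BandScaler", representation(mean = "numeric", sd = "numeric"))

setValidity("BandScaler", function(object) {
  if (length(object@mean) != length(object@sd)) return("mean and sd lengths differ")
  if (any(object@sd <= 0)) return("all band standard deviations must be > 0")
  TRUE
})

#' Classifier models
#'
#' Virtual parent of the two model kinds. Both record the spectral
#' normalization they were trained with ("none" or "snv") and refuse inputs
#' with mismatched provenance, and the identity of the subjects they were
#' trained on.
#'
#' @slot classSet class set predicted over.
#' @slot normalization "none" or "snv".
#' @slot trainSubjects subjects whose pixels entered training.
#' @exportClass ClassifierModel
setClass("ClassifierModel", representation("VIRTUAL",
  classSet = "TissueClassSet", normalization = "character",
  trainSubjects = "character"))

#' @describeIn ClassifierModel-class the 3D convolutional network: layer
#'   descriptors, parameter list and training log.
#' @slot arch architecture descriptor from [cnnArchitecture()].
#' @slot params list of weight matrices/bias vectors per layer.
#' @slot trained logical; FALSE until [trainCNN()] has run.
#' @slot log data.frame of (epoch, loss) from training.
#' @exportClass CNNModel
setClass("CNNModel", contains = "ClassifierModel",
  representation(arch = "list", params = "list", trained = "logical", log = "data.frame"))

#' @describeIn ClassifierModel-class RBF-kernel SVM on per-wavelength
#'   features; stores its band scaler so inference cannot bypass it.
#' @slot fit fitted e1071::svm object.
#' @slot scaler the [BandScaler-class] fitted on the training features.
#' @exportClass SVMModel
setClass("SVMModel", contains = "ClassifierModel",
  representation(fit = "ANY", scaler = "BandScaler"))

#' Cross-validation report for one model configuration
#'
#' @slot configuration label such as "CNN" or "SVM+SNV".
#' @slot folds list of per-fold results (held-out subject, truth, predictions,
#'   score matrix, confusion, per-class metrics).
#' @slot pooledConfusion confusion over all folds' test pixels.
#' @slot perClass per-fold x class matrices for sensitivity/specificity/dsc.
#' @slot summary data.frame of per-class mean, sd and standard error per metric.
#' @slot roc per-class pooled ROC data.
#' @slot seed seed the run used.
#' @exportClass CVReport
setClass("CVReport",
  representation(configuration = "character", folds = "list",
                 pooledConfusion = "list", perClass = "list",
                 summary = "data.frame", roc = "list", seed = "integer"))

setMethod("show", "TissueClassSet", function(object) {
  cat(sprintf("TissueClassSet with %d classes: %s\n", length(object@labels),
              paste(sprintf("%s=%d", object@labels, object@codes), collapse = ", ")))
})

setMethod("show", "HSICube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HSICube %s: %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              object@subjectId, d[1], d[2], d[3],
              min(object@wavelengths), max(object@wavelengths)))
})

setMethod("show", "AnnotationMask", function(object) {
  cat(sprintf("AnnotationMask %d x %d: %d annotated pixels (%d classes present)\n",
              nrow(object@labels), ncol(object@labels), sum(object@labels > 0L),
              length(setdiff(unique(as.vector(object@labels)), 0L))))
})

setMethod("show", "SubVolumeDataset", function(object) {
  cnt <- classCounts(object)
  cat(sprintf("SubVolumeDataset: %d samples, window %d, %d bands, normalization '%s'\n",
              nrow(object@volumes), object@window, length(object@wavelengths),
              object@normalization))
  cat("  per-class counts:", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
})

setMethod("show", "CNNModel", function(object) {
  cat(sprintf("CNNModel (%strained), %d trainable parameters, normalization '%s'\n",
              if (object@trained) "" else "un", countParameters(object),
              object@normalization))
})

setMethod("show", "SVMModel", function(object) {
  cat(sprintf("SVMModel (RBF, C=%g), %d support vectors, normalization '%s'\n",
              object@fit$cost, sum(object@fit$nSV), object@normalization))
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport '%s': %d folds\n", object@configuration, length(object@folds)))
  print(object@summary)
})
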