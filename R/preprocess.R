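#' Standard normal variate (SNV) normalization of a spectral curve
#'
#' Transforms one curve to zero mean and unit standard deviation, making it
#' invariant to positive affine (gain/offset) illumination effects. A
#' constant curve has no spectral shape to preserve and is an error, never a
#' silent division.
#'
#' @param curve numeric vector of length >= 2.
#' @return the normalized curve (mean 0, sd 1).
#' @export
snvNormalize <- function(curve) {
  if (length(curve) < 2L) stop("SNV needs at least 2 bands")
  s <- sd(curve)
  if (!is.finite(s) || s == 0)
    stop("degenerate (constant) spectral curve: SNV undefined")
  (curve - mean(curve)) / s
}

#' SNV-normalize every pixel of a cube
#'
#' Applies [snvNormalize()] independently to each pixel's spectral curve.
#' Any constant-spectrum pixel is an error naming its coordinates.
#'
#' @param cube an [HSICube-class].
#' @return a new [HSICube-class] with per-pixel mean 0 / sd 1 spectra.
#' @export
snvNormalizeCube <- function(cube) {
  stopifnot(is(cube, "HSICube"))
  d <- dim(cube@data)
  flat <- matrix(cube@data, d[1L] * d[2L], d[3L])    # pixels x bands
  mu <- rowMeans(flat)
  sdv <- sqrt(rowSums((flat - mu)^2) / (d[3L] - 1L))
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad)) {
    r <- (bad[1L] - 1L) %% d[1L] + 1L
    c <- (bad[1L] - 1L) %/% d[1L] + 1L
    stop(sprintf("constant spectrum at pixel (row %d, col %d): SNV undefined", r, c))
  }
  out <- (flat - mu) / sdv
  HSICube(array(out, dim = d), cube@wavelengths, cube@subjectId)
}

#' Fit per-band auto-scaling (mean centering, unit variance)
#'
#' Estimates per-band mean and standard deviation from training curves only.
#' A zero-variance band cannot be scaled and is an error naming the band.
#'
#' @param curves numeric matrix, one curve per row (n x B), n >= 2.
#' @return a [BandScaler-class].
#' @export
fitBandScaler <- function(curves) {
  curves <- as.matrix(curves)
  if (nrow(curves) < 2L) stop("need at least 2 curves to fit a band scaler")
  mu <- colMeans(curves)
  sdv <- apply(curves, 2L, sd)
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad))
    stop(sprintf("zero-variance band(s): %s", paste(bad, collapse = ", ")))
  new("BandScaler", mean = mu, sd = sdv)
}

#' Apply (or invert) a fitted band scaler
#'
#' @param scaler a [BandScaler-class].
#' @param curves numeric vector (length B) or matrix (n x B).
#' @param inverse undo the scaling instead.
#' @return scaled curve(s), same shape as the input.
#' @export
applyBandScaler <- function(scaler, curves, inverse = FALSE) {
  vec <- is.null(dim(curves))
  m <- if (vec) matrix(curves, nrow = 1L) else as.matrix(curves)
  if (ncol(m) != length(scaler@mean))
    stop(sprintf("curve has %d bands but scaler was fitted on %d",
                 ncol(m), length(scaler@mean)))
  out <- if (inverse) sweep(sweep(m, 2L, scaler@sd, "*"), 2L, scaler@mean, "+")
         else sweep(sweep(m, 2L, scaler@mean, "-"), 2L, scaler@sd, "/")
  if (vec) as.numeric(out) else out
}

#' Extract a sub-volume centered on a pixel
#'
#' Returns the w x w x B block centered on (row, col). Near image borders,
#' out-of-image positions are filled by edge replication; at interior pixels
#' the block reproduces the raw cube values exactly.
#'
#' @param cube an [HSICube-class].
#' @param center integer (row, col), 1-based, inside the cube.
#' @param window odd window side (default 5).
#' @return numeric array w x w x B.
#' @export
extractSubVolume <- function(cube, center, window = 5L) {
  stopifnot(is(cube, "HSICube"))
  if (window %% 2L == 0L) stop("window must be odd")
  d <- dim(cube@data)
  r <- center[1L]; c <- center[2L]
  if (r < 1L || r > d[1L] || c < 1L || c > d[2L])
    stop(sprintf("center (%d, %d) is outside the %d x %d cube", r, c, d[1L], d[2L]))
  half <- (window - 1L) %/% 2L
  rows <- pmin(pmax(r + (-half:half), 1L), d[1L])   # edge replication
  cols <- pmin(pmax(c + (-half:half), 1L), d[2L])
  cube@data[rows, cols, , drop = FALSE]
}

## flatten a w x w x B block to the dataset row layout:
## band fastest, then window column, then window row
flattenSubVolume <- function(block) {
  as.vector(aperm(block, c(3L, 2L, 1L)))
}

#' Assemble the labeled sub-volume dataset of a cohort
#'
#' One labeled w x w x B sub-volume per annotated pixel of every subject.
#' When `normalization = "snv"`, each pixel's curve is SNV-normalized before
#' patch extraction (equivalent, per pixel, to normalizing after
#' extraction). Dataset size always equals the annotated-pixel count.
#'
#' @param subjects list of subjects, each with elements `cube` and `mask`
#'   (e.g. from [makeCohort()]).
#' @param window odd spatial window (default 5).
#' @param normalization "none" or "snv".
#' @return a [SubVolumeDataset-class].
#' @export
buildDataset <- function(subjects, window = 5L, normalization = c("none", "snv")) {
  normalization <- match.arg(normalization)
  if (window %% 2L == 0L) stop("window must be odd")
  rows <- list(); labs <- list(); subs <- list(); ctrs <- list()
  wl <- NULL; cls <- NULL
  for (s in subjects) {
    cube <- s$cube; mask <- s$mask
    dc <- dim(cube@data)
    if (dc[1L] != nrow(mask@labels) || dc[2L] != ncol(mask@labels))
      stop(sprintf("subject %s: cube is %d x %d but mask is %d x %d",
                   cube@subjectId, dc[1L], dc[2L], nrow(mask@labels), ncol(mask@labels)))
    wl <- cube@wavelengths; cls <- mask@classSet
    if (normalization == "snv") cube <- snvNormalizeCube(cube)
    px <- annotatedPixels(mask)
    if (!nrow(px)) next
    mat <- matrix(0, nrow(px), window * window * length(wl))
    for (i in seq_len(nrow(px)))
      mat[i, ] <- flattenSubVolume(extractSubVolume(cube, c(px$row[i], px$col[i]), window))
    rows[[length(rows) + 1L]] <- mat
    labs[[length(labs) + 1L]] <- px$code
    subs[[length(subs) + 1L]] <- rep(cube@subjectId, nrow(px))
    ctrs[[length(ctrs) + 1L]] <- cbind(px$row, px$col)
  }
  if (is.null(cls)) cls <- tissueClasses()
  if (is.null(wl)) wl <- wavelengthGrid()
  vol <- if (length(rows)) do.call(rbind, rows)
         else matrix(0, 0L, window * window * length(wl))
  new("SubVolumeDataset", volumes = vol,
      labels = as.integer(unlist(labs)), subjects = as.character(unlist(subs)),
      centers = if (length(ctrs)) do.call(rbind, ctrs) else matrix(0L, 0L, 2L),
      window = as.integer(window), wavelengths = wl,
      normalization = normalization, classSet = cls)
}

## row-subset of a dataset (same window/normalization provenance)
subsetDataset <- function(dataset, idx) {
  new("SubVolumeDataset", volumes = dataset@volumes[idx, , drop = FALSE],
      labels = dataset@labels[idx], subjects = dataset@subjects[idx],
      centers = dataset@centers[idx, , drop = FALSE], window = dataset@window,
      wavelengths = dataset@wavelengths, normalization = dataset@normalization,
      classSet = dataset@classSet)
}

#' Per-class sample counts of a dataset
#'
#' @param dataset a [SubVolumeDataset-class].
#' @return named integer vector over all classes (zeros for absent classes).
#' @export
classCounts <- function(dataset) {
  cls <- dataset@classSet
  cnt <- vapply(cls@codes, function(code) sum(dataset@labels == code), integer(1))
  setNames(cnt, cls@labels)
}

#' Per-wavelength SVM features of sub-volumes
#'
#' Reduces each w x w x B sub-volume to a length-B feature vector: the
#' relative absorption of each wavelength at the center pixel of the
#' sub-volume, giving one feature dimension per wavelength. (The spatial
#' window thus carries no information on the SVM path; it is the CNN that
#' exploits spatial context.)
#'
#' @param x a [SubVolumeDataset-class], or a single w x w x B array.
#' @return numeric matrix n x B (or a length-B vector for a single block).
#' @export
svmFeatures <- function(x) {
  if (is(x, "SubVolumeDataset")) {
    B <- length(x@wavelengths)
    centerPos <- (as.integer(x@window)^2 - 1L) %/% 2L   # 0-based center slot
    x@volumes[, (centerPos * B + 1L):((centerPos + 1L) * B), drop = FALSE]
  } else {
    d <- dim(x)
    stopifnot(length(d) == 3L)
    as.numeric(x[(d[1L] + 1L) %/% 2L, (d[2L] + 1L) %/% 2L, ])
  }
}

#' Per-class spectral distribution statistics
#'
#' Mean curve and per-band standard deviation per class, computed from the
#' center-pixel curves of a dataset. Classes without samples are excluded
#' with a warning. Exportable to CSV ([writeSpectraCSV()]) and plottable as
#' per-class mean +/- sd band panels.
#'
#' @param dataset a [SubVolumeDataset-class].
#' @return named list per present class: list(mean, sd) curves of length B.
#' @export
classSpectralStats <- function(dataset) {
  cls <- dataset@classSet
  B <- length(dataset@wavelengths)
  w <- as.integer(dataset@window)
  centerPos <- ((w * w - 1L) %/% 2L)                # 0-based center window slot
  centerCols <- (centerPos * B + 1L):((centerPos + 1L) * B)
  out <- list()
  for (k in seq_along(cls@codes)) {
    idx <- which(dataset@labels == cls@codes[k])
    if (!length(idx)) {
      warning(sprintf("class '%s' has no samples; excluded from spectral stats",
                      cls@labels[k]))
      next
    }
    curves <- dataset@volumes[idx, centerCols, drop = FALSE]
    sdv <- if (length(idx) > 1L) apply(curves, 2L, sd) else numeric(B)
    out[[cls@labels[k]]] <- list(mean = colMeans(curves), sd = sdv)
  }
  out
}
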