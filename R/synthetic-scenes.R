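## Synthetic annotated hyperspectral surgery scenes.
##
## The generator emulates the statistical structure of in vivo neck-surgery
## hypercubes: smooth class-specific mean absorption curves with band-
## correlated intra-class deviation, per-pixel multiplicative/additive
## illumination effects (exactly the family SNV removes), a between-subject
## spectral shift (the dominant intra-class variation source), a high-variance
## specular metal class, severe class imbalance with nerves as thin
## curvilinear structures, and deliberate nerve-muscle-fat similarity.
## Curve shapes are package defaults constrained by the ordinal relations of
## real tissue spectra (nerve/muscle/fat similar; vein and skin most
## dissimilar; metal dominated by specular spikes) -- they are not
## measurements.

gaussBump <- function(t, center, width, amp) amp * exp(-((t - center) / width)^2)

#' Default spectral class models
#'
#' One model per class: a smooth mean absorption curve (sum of Gaussian bumps
#' over 500-1000 nm) plus variability scales. The defaults satisfy, by
#' construction: (a) the nerve/muscle/fat mean curves are mutually the
#' closest tissue pair set, (b) vein and skin are the most dissimilar from
#' the other tissues, and (c) metal has nonzero specular probability and the
#' largest sampled-curve variance.
#'
#' @param bands number of spectral bands.
#' @param wl wavelength grid (nm).
#' @param nerveMuscleSimilarity in [0,1]; morphs the nerve mean curve toward
#'   the muscle mean curve, controlling how confusable the two classes are.
#'   0 keeps the nerve base shape; 1 makes the means identical.
#' @return named list of 7 SpectralClassModel lists with fields
#'   `label`, `meanCurve`, `smoothDeviationScale`, `gainSd`, `offsetSd`,
#'   `noiseSd`, `specularProb`.
#' @export
defaultClassModels <- function(bands = 100L, wl = wavelengthGrid(bands),
                               nerveMuscleSimilarity = 0.8) {
  stopifnot(nerveMuscleSimilarity >= 0, nerveMuscleSimilarity <= 1)
  t <- (wl - 500) / 500

  muscle <- gaussBump(t, 0.15, 0.12, 0.90) + gaussBump(t, 0.55, 0.25, 0.45) + 0.30
  nerve0 <- gaussBump(t, 0.20, 0.14, 0.78) + gaussBump(t, 0.62, 0.22, 0.42) +
            gaussBump(t, 0.85, 0.10, 0.10) + 0.36
  nerve  <- (1 - nerveMuscleSimilarity) * nerve0 + nerveMuscleSimilarity * muscle
  fat    <- gaussBump(t, 0.16, 0.13, 0.72) + gaussBump(t, 0.58, 0.20, 0.32) +
            gaussBump(t, 0.86, 0.06, 0.28) + 0.24
  artery <- gaussBump(t, 0.08, 0.05, 0.78) + gaussBump(t, 0.155, 0.05, 0.82) +
            gaussBump(t, 0.50, 0.30, 0.12) + 0.22
  vein   <- gaussBump(t, 0.11, 0.09, 1.45) + gaussBump(t, 0.45, 0.16, 0.80) + 0.10
  skin   <- 1.35 * exp(-t / 0.30) + gaussBump(t, 0.75, 0.30, 0.10) + 0.14
  metal  <- 0.14 + 0.06 * t

  tissueModel <- function(label, mu) {
    list(label = label, meanCurve = mu,
         smoothDeviationScale = 0.025, gainSd = 0.04, offsetSd = 0.02,
         noiseSd = 0.015, specularProb = 0)
  }
  models <- list(
    artery = tissueModel("artery", artery),
    fat    = tissueModel("fat", fat),
    metal  = list(label = "metal", meanCurve = metal,
                  smoothDeviationScale = 0.06, gainSd = 0.20, offsetSd = 0.05,
                  noiseSd = 0.03, specularProb = 0.15),
    muscle = tissueModel("muscle", muscle),
    nerve  = tissueModel("nerve", nerve),
    skin   = tissueModel("skin", skin),
    vein   = tissueModel("vein", vein))
  for (m in models) stopifnot(all(is.finite(m$meanCurve)), m$specularProb >= 0,
                              m$specularProb <= 1)
  models
}

#' Scale the variability of a set of class models
#'
#' Multiplies every variability scale (smooth deviation, gain, offset, band
#' noise, specular probability) by `factor`, leaving the mean curves
#' untouched. `factor = 0` gives the fully separable limit in which every
#' pixel of a class is exactly its class mean curve.
#'
#' @param models class models from [defaultClassModels()].
#' @param factor nonnegative multiplier.
#' @return the scaled model list.
#' @export
scaleVariability <- function(models, factor) {
  stopifnot(factor >= 0)
  lapply(models, function(m) {
    m$smoothDeviationScale <- m$smoothDeviationScale * factor
    m$gainSd <- m$gainSd * factor
    m$offsetSd <- m$offsetSd * factor
    m$noiseSd <- m$noiseSd * factor
    m$specularProb <- min(1, m$specularProb * factor)
    m
  })
}

## Smooth band-correlated random curve: weighted sum of K Gaussian basis
## bumps with standard-normal coefficients, unit-normalized so `scale` is an
## amplitude in absorption units.
smoothDeviation <- function(bands, scale, nBasis = 6L) {
  if (scale <= 0) return(numeric(bands))
  t <- seq(0, 1, length.out = bands)
  centers <- seq(0.05, 0.95, length.out = nBasis)
  basis <- vapply(centers, function(c0) exp(-((t - c0) / 0.18)^2), numeric(bands))
  dev <- basis %*% rnorm(nBasis)
  scale * as.numeric(dev) / sqrt(mean(colSums(basis^2) / bands))
}

#' Sample one spectral curve from a class model
#'
#' Draws `gain * (mean + subjectShift + smooth deviation) + offset + noise`,
#' with lognormal gain around 1 and Gaussian offset around 0 -- the
#' multiplicative/additive illumination family that SNV normalization
#' removes. For metal, with probability `specularProb` a large positive
#' specular spike replaces the curve shape. Uses R's global RNG; seed the
#' stream for determinism.
#'
#' @param model a SpectralClassModel (see [defaultClassModels()]).
#' @param subjectShift length-B between-subject shift curve (0 for none).
#' @return numeric curve of length B.
#' @export
sampleCurve <- function(model, subjectShift = 0) {
  B <- length(model$meanCurve)
  if (model$specularProb > 0 && runif(1) < model$specularProb) {
    t <- seq(0, 1, length.out = B)
    amp <- runif(1, 2.5, 4.5)
    return(amp * (0.7 + 0.3 * exp(-((t - runif(1, 0.2, 0.8)) / 0.3)^2)) +
           rnorm(B, 0, model$noiseSd))
  }
  gain <- exp(rnorm(1, 0, model$gainSd))
  offset <- rnorm(1, 0, model$offsetSd)
  dev <- smoothDeviation(B, model$smoothDeviationScale)
  gain * (model$meanCurve + subjectShift + dev) + offset + rnorm(B, 0, model$noiseSd)
}

#' Scene configuration
#'
#' Geometry and spectral parameters of a synthetic surgical scene: a skin
#' background, a central muscle block with a subcutaneous-fat margin, artery
#' and vein tubes flanking a thin nerve (the neurovascular bundle), and a
#' metal retractor bar. Nerves are the thinnest structures by construction.
#'
#' @param height,width scene size in pixels (default 64 x 64, a desk-scale
#'   stand-in for the camera's 640 x 476 frame).
#' @param bands spectral bands.
#' @param vesselWidth,nerveWidth widths in pixels of vessels and nerve;
#'   `nerveWidth <= vesselWidth` is enforced.
#' @param classModels per-class spectral models.
#' @param subjectEffectSd between-subject smooth spectral shift scale.
#' @param annotationFractions named per-class fraction of region pixels that
#'   receive an annotation (sparse, conservative annotation emulation). The
#'   defaults reproduce severe class imbalance: skin dominates, nerve is
#'   rarest.
#' @param opticalBlur apply a fixed 3 x 3 point-spread blur to every band
#'   (camera optics emulation). Partial-volume mixing is what makes thin
#'   structures intrinsically hard: a 1-pixel nerve keeps only ~60 percent of
#'   its own signal, the rest coming from the surrounding tissue.
#' @param annotationErosion number of erosion passes applied to a region
#'   before annotating: annotations stay this many pixels away from region
#'   borders where the region is thick enough (conservative-annotator
#'   emulation); thin structures that erosion would erase keep their full
#'   region.
#' @param seed integer seed; the whole cohort is a pure function of
#'   (config, seed).
#' @return a `SceneConfig` list.
#' @export
sceneConfig <- function(height = 64L, width = 64L, bands = 100L,
                        vesselWidth = 3L, nerveWidth = 1L,
                        classModels = defaultClassModels(bands),
                        subjectEffectSd = 0.02,
                        annotationFractions = c(artery = 0.50, fat = 0.07,
                                                metal = 0.30, muscle = 0.04,
                                                nerve = 0.50, skin = 0.15,
                                                vein = 0.50),
                        opticalBlur = TRUE,
                        annotationErosion = 2L,
                        seed = 1L) {
  if (nerveWidth > vesselWidth)
    stop("nerveWidth must not exceed vesselWidth: nerves are the thinnest structures")
  if (height < 32L || width < 32L)
    stop("scene too small to place all 7 classes (need at least 32 x 32)")
  structure(list(height = as.integer(height), width = as.integer(width),
                 bands = as.integer(bands), vesselWidth = as.integer(vesselWidth),
                 nerveWidth = as.integer(nerveWidth), classModels = classModels,
                 subjectEffectSd = subjectEffectSd,
                 annotationFractions = annotationFractions,
                 opticalBlur = isTRUE(opticalBlur),
                 annotationErosion = as.integer(annotationErosion),
                 seed = as.integer(seed)),
            class = "SceneConfig")
}

## deterministic per-(seed, subject) stream seed, kept below 2^31
subjectSeed <- function(seed, subjectIndex) {
  as.integer((as.numeric(seed) * 1000003 + subjectIndex * 7919) %% 2147483647)
}

## region layout: integer H x W matrix of class codes (every pixel belongs
## to some class; annotation sparsity comes later)
renderRegions <- function(config) {
  H <- config$height; W <- config$width
  cls <- tissueClasses()
  code <- setNames(cls@codes, cls@labels)
  lab <- matrix(code[["skin"]], H, W)

  # central muscle block with fat margin
  r0 <- round(H * 0.30); r1 <- round(H * 0.92)
  c0 <- round(W * 0.15); c1 <- round(W * 0.85)
  fm <- max(2L, round(min(H, W) * 0.06))   # fat margin thickness
  lab[max(1, r0 - fm):min(H, r1 + fm), max(1, c0 - fm):min(W, c1 + fm)] <- code[["fat"]]
  lab[r0:r1, c0:c1] <- code[["muscle"]]

  # vessels and nerve: vertical sinusoidal tubes inside the muscle block;
  # artery left, nerve center (thinnest), vein right -- a neurovascular bundle
  rows <- r0:r1
  phase <- runif(3, 0, 2 * pi)
  drawTube <- function(lab, centerCol, widthPx, phi, codeVal) {
    amp <- W * 0.03
    cc <- centerCol + amp * sin(2 * pi * (rows - r0) / length(rows) + phi)
    half <- (widthPx - 1L) / 2
    for (i in seq_along(rows)) {
      lo <- max(1L, round(cc[i] - half)); hi <- min(W, round(cc[i] + half))
      lab[rows[i], lo:hi] <- codeVal
    }
    lab
  }
  lab <- drawTube(lab, W * 0.38, config$vesselWidth, phase[1L], code[["artery"]])
  lab <- drawTube(lab, W * 0.62, config$vesselWidth, phase[2L], code[["vein"]])
  lab <- drawTube(lab, W * 0.50, config$nerveWidth, phase[3L], code[["nerve"]])

  # metal retractor bar along the top
  lab[max(1, round(H * 0.03)):max(2, round(H * 0.10)),
      round(W * 0.10):round(W * 0.90)] <- code[["metal"]]
  lab
}

## fixed 3x3 point-spread blur per band (edge-replicated); weights
## center 0.4, edge 0.1, corner 0.05
psfBlurCube <- function(data) {
  H <- dim(data)[1L]; W <- dim(data)[2L]
  up <- c(1L, seq_len(H - 1L)); dn <- c(seq_len(H - 1L) + 1L, H)
  lf <- c(1L, seq_len(W - 1L)); rt <- c(seq_len(W - 1L) + 1L, W)
  0.4 * data +
    0.1 * (data[up, , , drop = FALSE] + data[dn, , , drop = FALSE] +
           data[, lf, , drop = FALSE] + data[, rt, , drop = FALSE]) +
    0.05 * (data[up, lf, , drop = FALSE] + data[up, rt, , drop = FALSE] +
            data[dn, lf, , drop = FALSE] + data[dn, rt, , drop = FALSE])
}

## 4-neighbour erosion of a binary mask
erodeBinary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-H, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -W, drop = FALSE])
  m & up & dn & lf & rt
}

## sparse annotation: eroded core (where it survives) then per-class subsample
annotateRegions <- function(regions, config) {
  cls <- tissueClasses()
  out <- matrix(0L, nrow(regions), ncol(regions))
  for (k in seq_along(cls@codes)) {
    codeVal <- cls@codes[k]; labName <- cls@labels[k]
    m <- regions == codeVal
    if (!any(m)) next
    core <- m
    # stop eroding when the core would collapse to a sliver (thin structures
    # keep their full region; ring/bar shapes stop at a usable core)
    minCore <- max(8L, round(0.15 * sum(m)))
    for (it in seq_len(config$annotationErosion)) {
      shrunk <- erodeBinary(core)
      if (sum(shrunk) < minCore) break
      core <- shrunk
    }
    idx <- which(core)
    frac <- config$annotationFractions[[labName]]
    nKeep <- max(1L, round(length(idx) * frac))
    keep <- sample(idx, nKeep)
    out[keep] <- codeVal
  }
  out
}

#' Generate one synthetic subject
#'
#' Renders the scene geometry, samples every pixel's spectrum from its class
#' model with a per-subject shared smooth spectral shift, and annotates a
#' sparse subset of each region. Deterministic given (config, subjectIndex):
#' the RNG stream is derived from `config$seed` and the subject index.
#'
#' @param config a [sceneConfig()].
#' @param subjectIndex 1-based subject number.
#' @return list with elements `cube` ([HSICube-class]), `mask`
#'   ([AnnotationMask-class]) and `subjectId`.
#' @export
makeSubject <- function(config, subjectIndex) {
  stopifnot(inherits(config, "SceneConfig"))
  sid <- sprintf("S%02d", subjectIndex)
  set.seed(subjectSeed(config$seed, subjectIndex))
  H <- config$height; W <- config$width; B <- config$bands
  wl <- wavelengthGrid(B)
  cls <- tissueClasses()

  regions <- renderRegions(config)
  # between-subject spectral shift: mostly shared across tissues (common
  # illumination/physiology), with a small tissue-specific residual
  shared <- smoothDeviation(B, config$subjectEffectSd * sqrt(0.9))
  shifts <- lapply(cls@labels, function(l)
    shared + smoothDeviation(B, config$subjectEffectSd * sqrt(0.1)))
  names(shifts) <- cls@labels

  data <- array(0, dim = c(H, W, B))
  flat <- matrix(0, H * W, B)
  regVec <- as.vector(regions)
  for (k in seq_along(cls@codes)) {
    idx <- which(regVec == cls@codes[k])
    if (!length(idx)) next
    model <- config$classModels[[cls@labels[k]]]
    sh <- shifts[[cls@labels[k]]]
    for (i in idx) flat[i, ] <- sampleCurve(model, sh)
  }
  data[] <- flat   # H*W x B column-major fill matches array (H, W, B)
  if (config$opticalBlur) data <- psfBlurCube(data)

  mask <- AnnotationMask(annotateRegions(regions, config), cls)
  present <- setdiff(unique(as.vector(mask@labels)), 0L)
  if (length(present) < length(cls@codes))
    stop("scene too small: not every class received an annotated pixel")
  list(cube = HSICube(data, wl, sid), mask = mask, subjectId = sid,
       regions = regions)
}

#' Generate a cohort of synthetic subjects
#'
#' Independent subject-level spectral shifts, distinct subject ids,
#' deterministic given the config seed. At least 2 subjects are required
#' (leave-one-patient-out cross-validation is otherwise undefined).
#'
#' @param config a [sceneConfig()].
#' @param nSubjects cohort size (default 8).
#' @return list of subjects as returned by [makeSubject()].
#' @export
makeCohort <- function(config, nSubjects = 8L) {
  if (nSubjects < 2L) stop("a cohort needs at least 2 subjects for LOPOCV")
  lapply(seq_len(nSubjects), function(i) makeSubject(config, i))
}

#' Write a subject to disk in the package's exchange formats
#'
#' ENVI cube (`<id>.raw` + `.hdr`) and PNG mask + JSON sidecar.
#'
#' @param subject a [makeSubject()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of the paths written.
#' @export
writeSubject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cubePath <- file.path(dir, paste0(subject$subjectId, ".raw"))
  maskPath <- file.path(dir, paste0(subject$subjectId, "_mask.png"))
  writeCube(subject$cube, cubePath)
  writeMask(subject$mask, maskPath)
  c(cube = cubePath, header = paste0(cubePath, ".hdr"),
    mask = maskPath, classmap = paste0(maskPath, ".json"))
}
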