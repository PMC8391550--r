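#' The seven-class tissue set
#'
#' Returns the fixed class set used throughout: artery, fat, metal, muscle,
#' nerve, skin, vein, coded 1..7 in alphabetical order. Code 0 is reserved
#' for unlabeled pixels. Display colors follow surgical-anatomy convention
#' (artery red, vein blue, nerve green, ...).
#'
#' @return A [TissueClassSet-class].
#' @examples
#' tissueClasses()
#' @export
tissueClasses <- function() {
  new("TissueClassSet",
      labels = c("artery", "fat", "metal", "muscle", "nerve", "skin", "vein"),
      codes  = 1:7,
      colors = c(artery = "#D62728", fat = "#F5D033", metal = "#9A9A9A",
                 muscle = "#8C3B1B", nerve = "#2CA02C", skin = "#F2A07B",
                 vein = "#1F77B4"))
}

#' @rdname tissueClasses
#' @param x a TissueClassSet.
#' @export
classLabels <- function(x) x@labels

#' @rdname tissueClasses
#' @export
classCodes <- function(x) x@codes

#' @rdname tissueClasses
#' @export
classColors <- function(x) setNames(x@colors, x@labels)

#' Default wavelength grid
#'
#' Band centers for a B-band acquisition spanning 500-1000 nm, equally
#' spaced, matching visible-green to near-infrared push-broom systems.
#'
#' @param bands number of bands (default 100).
#' @param from,to range in nm.
#' @return numeric vector of band centers.
#' @export
wavelengthGrid <- function(bands = 100L, from = 500, to = 1000) {
  stopifnot(bands >= 2L, to > from)
  seq(from, to, length.out = bands)
}

#' Construct a hyperspectral cube
#'
#' @param data H x W x B array of finite relative-absorption values.
#' @param wavelengths band centers in nm (length B).
#' @param subjectId subject identifier.
#' @return An [HSICube-class].
#' @export
HSICube <- function(data, wavelengths = wavelengthGrid(dim(data)[3L]),
                    subjectId = "subject") {
  new("HSICube", data = data, wavelengths = as.numeric(wavelengths),
      subjectId = as.character(subjectId))
}

#' Cube and mask accessors
#'
#' @param x an HSICube or AnnotationMask.
#' @return `cubeData`: the H x W x B array; `wavelengths`: band centers;
#'   `subjectId`: the subject string; `maskLabels`: the integer label matrix;
#'   `classSet`: the associated [TissueClassSet-class].
#' @export
cubeData <- function(x) x@data

#' @rdname cubeData
#' @export
wavelengths <- function(x) x@wavelengths

#' @rdname cubeData
#' @export
subjectId <- function(x) x@subjectId

#' @rdname cubeData
#' @export
maskLabels <- function(x) x@labels

#' @rdname cubeData
#' @export
classSet <- function(x) x@classSet

#' Construct an annotation mask
#'
#' @param labels integer H x W matrix, 0 = unlabeled.
#' @param classSet class set the codes refer to.
#' @return An [AnnotationMask-class].
#' @export
AnnotationMask <- function(labels, classSet = tissueClasses()) {
  storage.mode(labels) <- "integer"
  new("AnnotationMask", labels = labels, classSet = classSet)
}

## ---- ENVI hypercube I/O ----------------------------------------------------
## Minimal ENVI dialect: lowercase keys, band-sequential (bsq) interleave,
## 32-bit float (data type 4), little endian (byte order 0). Header is the
## text file <path>.hdr; binary is <path> itself.

enviFormatError <- function(fmt, ...) {
  stop(structure(class = c("enviFormatError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

parseEnviHeader <- function(hdrPath) {
  txt <- readLines(hdrPath, warn = FALSE)
  if (!length(txt) || !grepl("^ENVI", txt[1L]))
    enviFormatError("'%s' is not an ENVI header (missing ENVI magic line)", hdrPath)
  # join multi-line { ... } blocks onto one logical line each
  lines <- character(); buf <- ""
  for (ln in txt[-1L]) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    nOpen <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    nClose <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    if (nOpen == nClose) { if (nzchar(trimws(buf))) lines <- c(lines, buf); buf <- "" }
  }
  fields <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    fields[[key]] <- val
  }
  fields
}

#' Read a hypercube from an ENVI header/binary pair
#'
#' Reads the lowercase-key, band-sequential, 32-bit-float ENVI dialect
#' written by [writeCube()]. The wavelength list in the header becomes the
#' cube's wavelength axis.
#'
#' @param path path to the binary file; the header is `<path>.hdr`.
#' @param subjectId subject identifier to attach (default: header field
#'   `subject id` if present, else the file name).
#' @return An [HSICube-class].
#' @export
readCube <- function(path, subjectId = NULL) {
  hdrPath <- paste0(path, ".hdr")
  if (!file.exists(hdrPath)) enviFormatError("header file '%s' not found", hdrPath)
  if (!file.exists(path)) enviFormatError("binary file '%s' not found", path)
  h <- parseEnviHeader(hdrPath)
  need <- c("samples", "lines", "bands", "interleave", "data type", "wavelength")
  missing <- setdiff(need, names(h))
  if (length(missing))
    enviFormatError("header is missing required field(s): %s", paste(missing, collapse = ", "))
  W <- as.integer(h[["samples"]]); H <- as.integer(h[["lines"]]); B <- as.integer(h[["bands"]])
  if (h[["interleave"]] != "bsq")
    enviFormatError("unsupported interleave '%s' (field 'interleave'; only 'bsq' is supported)",
                    h[["interleave"]])
  if (as.integer(h[["data type"]]) != 4L)
    enviFormatError("unsupported data type '%s' (field 'data type'; only 4 = float32)",
                    h[["data type"]])
  wl <- as.numeric(strsplit(gsub("[{}]", "", h[["wavelength"]]), ",")[[1L]])
  if (length(wl) != B)
    enviFormatError("field 'bands' declares %d bands but 'wavelength' lists %d values", B, length(wl))
  n <- H * W * B
  raw <- readBin(path, "numeric", n = n + 1L, size = 4L, endian = "little")
  if (length(raw) != n)
    enviFormatError("binary size mismatch: expected %d float32 values, found %d", n, length(raw))
  # bsq: band-sequential planes, each plane W samples (columns) fastest
  arr <- aperm(array(raw, dim = c(W, H, B)), c(2L, 1L, 3L))
  if (is.null(subjectId))
    subjectId <- if (!is.null(h[["subject id"]])) h[["subject id"]] else basename(path)
  HSICube(arr, wl, subjectId)
}

#' Write a hypercube as an ENVI header/binary pair
#'
#' Writes `<path>` (raw little-endian float32, band-sequential) and
#' `<path>.hdr`. Output bytes are deterministic for identical input.
#'
#' @param cube an [HSICube-class]; all values must be finite.
#' @param path output binary path.
#' @return `path`, invisibly.
#' @export
writeCube <- function(cube, path) {
  stopifnot(is(cube, "HSICube"))
  validObject(cube)
  d <- dim(cube@data)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2L]),
           sprintf("lines = %d", d[1L]),
           sprintf("bands = %d", d[3L]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           "interleave = bsq",
           "byte order = 0",
           sprintf("subject id = %s", cube@subjectId),
           sprintf("wavelength = {%s}",
                   paste(format(cube@wavelengths, trim = TRUE, digits = 12),
                         collapse = ", ")))
  con <- file(paste0(path, ".hdr"), "wb")  # binary mode: fixed \n, deterministic bytes
  writeLines(hdr, con, sep = "\n")
  close(con)
  # bsq plane order with samples (columns) fastest
  flat <- as.vector(aperm(cube@data, c(2L, 1L, 3L)))
  con <- file(path, "wb")
  tryCatch(writeBin(flat, con, size = 4L, endian = "little"),
           finally = close(con))
  invisible(path)
}

## ---- Mask I/O --------------------------------------------------------------

#' Read an annotation mask (indexed PNG + JSON class map)
#'
#' The mask is an 8-bit grayscale PNG whose pixel values are the class codes
#' (0 = unlabeled); the sidecar is a JSON object mapping code to class name.
#' Any code in the image but absent from the sidecar is an error.
#'
#' @param path PNG path.
#' @param classMapPath JSON sidecar path (default `<path>.json`).
#' @param classSet class set to validate against.
#' @return An [AnnotationMask-class].
#' @export
readMask <- function(path, classMapPath = paste0(path, ".json"),
                     classSet = tissueClasses()) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  labels <- matrix(as.integer(round(img * 255)), nrow = nrow(img))
  cmap <- jsonlite::fromJSON(classMapPath)
  known <- as.integer(names(cmap))
  present <- setdiff(unique(as.vector(labels)), 0L)
  bad <- setdiff(present, known)
  if (length(bad))
    stop(sprintf("mask contains code(s) not in the class map sidecar: %s",
                 paste(sort(bad), collapse = ", ")))
  # sidecar names must agree with the class set at those codes
  for (code in known) {
    want <- classSet@labels[match(code, classSet@codes)]
    if (!is.na(want) && !identical(unname(cmap[[as.character(code)]]), want))
      stop(sprintf("sidecar maps code %d to '%s' but the class set says '%s'",
                   code, cmap[[as.character(code)]], want))
  }
  AnnotationMask(labels, classSet)
}

#' Write an annotation mask (indexed PNG + JSON class map)
#'
#' @param mask an [AnnotationMask-class].
#' @param path output PNG path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "AnnotationMask"))
  validObject(mask)
  png::writePNG(mask@labels / 255, path)
  cmap <- as.list(setNames(mask@classSet@labels, mask@classSet@codes))
  jsonlite::write_json(cmap, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Enumerate annotated pixels
#'
#' Returns all pixels with a nonzero class code in row-major order (row 1
#' left to right, then row 2, ...). Coordinates are 1-based (row, col).
#'
#' @param mask an [AnnotationMask-class].
#' @return data.frame with columns row, col, code.
#' @export
annotatedPixels <- function(mask) {
  stopifnot(is(mask, "AnnotationMask"))
  lab <- mask@labels
  idx <- which(t(lab) != 0L)          # transpose => row-major enumeration
  W <- ncol(lab)
  row <- (idx - 1L) %/% W + 1L
  col <- (idx - 1L) %% W + 1L
  data.frame(row = row, col = col,
             code = lab[cbind(row, col)])
}

#' Export spectra to CSV
#'
#' Writes a wavelength column plus one column per curve.
#'
#' @param curves numeric matrix, one curve per column (length B each), or a
#'   single numeric vector.
#' @param wl wavelengths (length B).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectraCSV <- function(curves, wl, path) {
  curves <- as.matrix(curves)
  stopifnot(nrow(curves) == length(wl))
  df <- data.frame(wavelength = wl, curves, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
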