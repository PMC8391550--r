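test_that("SNV gives mean 0 / sd 1, is idempotent and affine-invariant", {
  set.seed(1)
  x <- rnorm(100, mean = 3, sd = 0.4)
  y <- snvNormalize(x)
  expect_equal(mean(y), 0, tolerance = 1e-12)
  expect_equal(sd(y), 1, tolerance = 1e-12)
  expect_equal(snvNormalize(y), y, tolerance = 1e-12)
  expect_equal(snvNormalize(2.5 * x + 7), y, tolerance = 1e-12)
  expect_error(snvNormalize(rep(1, 50)), "degenerate")
  expect_error(snvNormalize(3), "2 bands")
})

test_that("cube SNV normalizes every pixel independently and keeps dims", {
  cube <- randomCube(6L, 5L, 40L, seed = 2)
  out <- snvNormalizeCube(cube)
  expect_identical(dim(cubeData(out)), dim(cubeData(cube)))
  flat <- matrix(cubeData(out), 30, 40)
  expect_equal(rowMeans(flat), rep(0, 30), tolerance = 1e-12)
  expect_equal(apply(flat, 1, sd), rep(1, 30), tolerance = 1e-12)
  # scaling the cube does not change the result
  scaled <- HSICube(2 * cubeData(cube), wavelengths(cube), subjectId(cube))
  expect_equal(cubeData(snvNormalizeCube(scaled)), cubeData(out), tolerance = 1e-12)
  # constant pixel is pinpointed
  bad <- cubeData(cube); bad[3, 2, ] <- 1
  expect_error(snvNormalizeCube(HSICube(bad, wavelengths(cube))), "row 3, col 2")
})

test_that("band scaler standardizes its own training set and nothing else", {
  set.seed(3)
  curves <- matrix(rnorm(12 * 20, mean = 5), 12, 20)
  sc <- fitBandScaler(curves)
  scaled <- applyBandScaler(sc, curves)
  expect_equal(colMeans(scaled), rep(0, 20), tolerance = 1e-12)
  expect_equal(apply(scaled, 2, sd), rep(1, 20), tolerance = 1e-12)

  # applied to held-out curves the band means are not 0 in general
  toyTrain <- rbind(c(0, 1), c(2, 3), c(4, 8))
  toyTest <- rbind(c(10, 2), c(12, 4))
  scT <- fitBandScaler(toyTrain)
  heldOut <- applyBandScaler(scT, toyTest)
  expect_equal(colMeans(heldOut), c(4.5, -1 / sqrt(13)), tolerance = 1e-10)
  expect_false(any(abs(colMeans(heldOut)) < 1e-8))

  expect_error(fitBandScaler(rbind(c(1, 2), c(1, 5))), "band")
  expect_error(fitBandScaler(matrix(1:5, 1)), "at least 2")
  expect_error(applyBandScaler(sc, rnorm(7)), "bands")
})

test_that("band scaler maps mu -> 0 and mu + sigma -> 1 and inverts cleanly", {
  sc <- fitBandScaler(matrix(rnorm(50), 10, 5))
  expect_equal(applyBandScaler(sc, sc@mean), rep(0, 5))
  expect_equal(applyBandScaler(sc, sc@mean + sc@sd), rep(1, 5))
  x <- rnorm(5)
  expect_equal(applyBandScaler(sc, applyBandScaler(sc, x), inverse = TRUE), x,
               tolerance = 1e-12)
})

test_that("sub-volume extraction is exact in the interior and replicated at edges", {
  cube <- randomCube(10L, 10L, 20L, seed = 4)
  block <- extractSubVolume(cube, c(5L, 6L), 5L)
  expect_identical(dim(block), c(5L, 5L, 20L))
  expect_identical(block, cubeData(cube)[3:7, 4:8, ])

  corner <- extractSubVolume(cube, c(1L, 1L), 5L)
  expect_identical(dim(corner), c(5L, 5L, 20L))
  # rows/cols below 1 replicate the first row/col
  expect_identical(corner[1, , ], corner[2, , ])
  expect_identical(corner[, 1, ], corner[, 2, ])

  # cube whose every band equals the pixel row index
  rowCube <- HSICube(array(rep(matrix(1:10, 10, 10), 20), dim = c(10, 10, 20)),
                     wavelengthGrid(20))
  patch <- extractSubVolume(rowCube, c(4L, 4L), 5L)
  expect_true(all(patch[3, , ] == 4))

  expect_error(extractSubVolume(cube, c(0L, 3L)), "outside")
  expect_error(extractSubVolume(cube, c(3L, 3L), 4L), "odd")
})

test_that("dataset size equals the annotated-pixel count with exact bookkeeping", {
  cohort <- smallCohort(2, seed = 6)
  nAnnot <- sum(vapply(cohort, function(s) sum(maskLabels(s$mask) > 0), numeric(1)))
  ds <- buildDataset(cohort, 5L, "none")
  expect_identical(nrow(ds@volumes), as.integer(nAnnot))
  gen <- unlist(lapply(cohort, function(s) maskLabels(s$mask)[maskLabels(s$mask) > 0]))
  expect_identical(unname(classCounts(ds)),
                   vapply(1:7, function(k) sum(gen == k), integer(1)))

  # empty masks give an empty dataset
  empt <- lapply(cohort, function(s)
    list(cube = s$cube, mask = AnnotationMask(matrix(0L, 40, 40))))
  expect_identical(nrow(buildDataset(empt, 5L, "none")@volumes), 0L)

  # mismatched dims are an error
  bad <- list(list(cube = cohort[[1]]$cube, mask = AnnotationMask(matrix(0L, 8, 8))))
  expect_error(buildDataset(bad, 5L, "none"), "mask is 8 x 8")
})

test_that("SNV-before-extraction equals per-pixel SNV of the center curve", {
  cohort <- smallCohort(1 + 1, seed = 8)[1]
  ds <- buildDataset(cohort, 5L, "snv")
  expect_identical(ds@normalization, "snv")
  B <- 100L
  centerCols <- (12L * B + 1L):(13L * B)
  centers <- ds@volumes[, centerCols]
  expect_equal(rowMeans(centers), rep(0, nrow(centers)), tolerance = 1e-10)
  expect_equal(apply(centers, 1, sd), rep(1, nrow(centers)), tolerance = 1e-10)
})

test_that("SVM features are the center pixel's per-wavelength curve", {
  # 3x3x2 toy block with known values: center (2,2) holds 5 and 50
  block <- array(c(1:4, 5, 6:9, 10 * c(1:4, 5, 6:9)), dim = c(3, 3, 2))
  expect_equal(svmFeatures(block), c(5, 50))

  cohort <- smallCohort(2, seed = 9)
  ds <- buildDataset(cohort, 5L, "none")
  f <- svmFeatures(ds)
  expect_identical(dim(f), c(nrow(ds@volumes), 100L))
  # brute-force check against direct cube lookup for the first samples
  cube <- cubeData(cohort[[1]]$cube)
  for (i in 1:3)
    expect_equal(f[i, ], cube[ds@centers[i, 1], ds@centers[i, 2], ],
                 tolerance = 1e-12)

  # spatially constant patch reduces to the (center) pixel's curve
  flatBlock <- array(rep(1:6, each = 9), dim = c(3, 3, 6))
  expect_equal(svmFeatures(flatBlock), as.numeric(1:6))
})

test_that("per-class spectral stats match direct computation", {
  cohort <- smallCohort(2, seed = 10)
  ds <- buildDataset(cohort, 5L, "none")
  stats <- classSpectralStats(ds)
  B <- 100L
  centerCols <- (12L * B + 1L):(13L * B)
  for (cl in names(stats)) {
    code <- match(cl, classLabels(ds@classSet))
    curves <- ds@volumes[ds@labels == code, centerCols, drop = FALSE]
    expect_equal(stats[[cl]]$mean, colMeans(curves), tolerance = 1e-12)
    expect_equal(stats[[cl]]$sd, apply(curves, 2, sd), tolerance = 1e-12)
  }
  # single-curve class: sd identically zero
  one <- hsinerve:::subsetDataset(ds, which(ds@labels == 5L)[1])
  w <- capture_warnings(s1 <- classSpectralStats(one))
  expect_true(any(grepl("excluded", w)))
  expect_identical(s1$nerve$sd, rep(0, B))
  # after SNV every class mean-of-means is ~0
  dsn <- buildDataset(cohort, 5L, "snv")
  sn <- classSpectralStats(dsn)
  for (cl in names(sn)) expect_lt(abs(mean(sn[[cl]]$mean)), 1e-10)
})
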