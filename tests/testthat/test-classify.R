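makeClusterDataset <- function(centers, perClass = 20L, spread = 0.05, seed = 1L) {
  # synthetic sub-volume dataset whose spatially-constant patches reduce to
  # the given 100-band cluster centers
  set.seed(seed)
  B <- 100L; w <- 5L
  rows <- list(); labs <- integer()
  for (k in seq_along(centers)) {
    for (i in seq_len(perClass)) {
      curve <- centers[[k]] + rnorm(B, 0, spread)
      rows[[length(rows) + 1L]] <- rep(curve, w * w)
      labs <- c(labs, k)
    }
  }
  new("SubVolumeDataset", volumes = do.call(rbind, rows), labels = labs,
      subjects = rep("T01", length(labs)),
      centers = matrix(1L, length(labs), 2), window = w,
      wavelengths = wavelengthGrid(B), normalization = "none",
      classSet = tissueClasses())
}

test_that("the SVM separates well-separated clusters perfectly", {
  t0 <- seq(0, 1, length.out = 100)
  centers <- list(sin(2 * pi * t0), 3 + 0 * t0, 5 * t0)
  ds <- makeClusterDataset(centers, perClass = 15L)
  model <- trainSVM(ds)
  pred <- classifyScores(predictScores(model, ds), model@classSet)
  expect_equal(mean(pred == ds@labels), 1.0)

  # the three cluster centers themselves are recovered
  centerDs <- makeClusterDataset(centers, perClass = 1L, spread = 0)
  predC <- classifyScores(predictScores(model, centerDs), model@classSet)
  expect_identical(predC, c(1L, 2L, 3L))

  # duplicate input gives identical scores
  s1 <- predictScores(model, centerDs)
  s2 <- predictScores(model, centerDs)
  expect_identical(s1, s2)
})

test_that("SVM training requires at least two classes and stores its scaler", {
  t0 <- seq(0, 1, length.out = 100)
  ds <- makeClusterDataset(list(t0), perClass = 10L)
  expect_error(trainSVM(ds), "two classes")

  ds2 <- makeClusterDataset(list(t0, 2 - t0), perClass = 10L)
  model <- trainSVM(ds2)
  expect_s4_class(model@scaler, "BandScaler")
  # the stored scaler is the one fitted on the training features
  expect_equal(model@scaler@mean, colMeans(svmFeatures(ds2)), tolerance = 1e-12)
})

test_that("SVM provenance: an SNV-trained model rejects raw inputs", {
  cohort <- smallCohort(2, seed = 17)
  dsSnv <- buildDataset(cohort, 5L, "snv")
  dsRaw <- buildDataset(cohort, 5L, "none")
  model <- trainSVM(dsSnv)
  expect_identical(model@normalization, "snv")
  expect_error(predictScores(model, dsRaw), "normalization")
})

test_that("classifyScores takes the argmax with ties to the lowest code", {
  expect_identical(classifyScores(c(0.1, 0.9, 0, 0, 0, 0, 0)), 2L)
  s <- c(0, 0, 0.7, 0, 0.7, 0, 0)
  expect_identical(classifyScores(s), 3L)
  expect_error(classifyScores(c(NaN, rep(0, 6))), "NaN")
  m <- rbind(c(1, rep(0, 6)), c(rep(0, 6), 1))
  expect_identical(classifyScores(m), c(1L, 7L))
})

test_that("predictImage predicts requested pixels and dense label maps", {
  cohort <- smallCohort(2, seed = 18, variability = 0)
  ds <- buildDataset(cohort, 5L, "none")
  model <- trainSVM(ds)
  subj <- cohort[[1]]

  px <- cbind(c(3L, 10L, 20L), c(5L, 12L, 33L))
  out <- predictImage(model, subj$cube, pixels = px)
  expect_identical(nrow(out$scores), 3L)
  expect_identical(sum(out$labels > 0L), 3L)

  annot <- predictImage(model, subj$cube, mask = subj$mask)
  expect_identical(nrow(annot$pixels), sum(maskLabels(subj$mask) > 0L))

  dense <- predictImage(model, subj$cube, pixels = "all")
  expect_identical(dim(dense$labels), c(40L, 40L))
  expect_true(all(dense$labels > 0L))

  expect_error(predictImage(model, subj$cube, pixels = cbind(99L, 1L)), "outside")
})

test_that("on a zero-variability cohort predictions equal the ground truth", {
  config <- sceneConfig(
    height = 40L, width = 40L, seed = 19L,
    classModels = scaleVariability(defaultClassModels(nerveMuscleSimilarity = 0), 0),
    subjectEffectSd = 0, opticalBlur = FALSE)
  cohort <- makeCohort(config, 3L)
  ds <- buildDataset(cohort, 5L, "none")
  train <- hsinerve:::subsetDataset(ds, ds@subjects != "S03")
  test <- hsinerve:::subsetDataset(ds, ds@subjects == "S03")

  svm <- trainSVM(train)
  predS <- classifyScores(predictScores(svm, test), svm@classSet)
  expect_equal(mean(predS == test@labels), 1.0)

  cnn <- trainCNN(buildCNN(seed = 2), train, epochs = 20L, seed = 2)
  predC <- classifyScores(predictScores(cnn, test), cnn@classSet)
  expect_gte(mean(predC == test@labels), 0.99)
  # a nerve pixel is classified as nerve
  expect_true(any(test@labels == 5L))
  expect_equal(predC[test@labels == 5L], test@labels[test@labels == 5L])
})
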