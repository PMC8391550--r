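test_that("the default network has exactly 32,628 parameters and 7 outputs", {
  arch <- cnnArchitecture(window = 5L, bands = 100L, nClasses = 7L)
  expect_identical(arch$nParams, 32628L)
  expect_identical(arch$layers$out$Fout, 7L)
  # 6 convolutional hidden layers + 1 fully connected hidden layer + output
  types <- vapply(arch$layers, `[[`, character(1), "type")
  expect_identical(unname(types), c(rep("conv", 6), "fc", "fc"))

  model <- buildCNN(seed = 1)
  expect_identical(countParameters(model), 32628)

  # impossible layer arithmetic is a construction error
  expect_error(cnnArchitecture(window = 3L), "nonpositive")
  expect_error(cnnArchitecture(window = 4L), "odd")
})

test_that("the untrained forward pass yields finite per-class scores", {
  model <- buildCNN(seed = 2)
  set.seed(1)
  X <- matrix(rnorm(2500 * 3), 2500, 3)
  logits <- hsinerve:::cnnForward(model@arch, model@params, X)$logits
  expect_identical(dim(logits), c(7L, 3L))
  expect_true(all(is.finite(logits)))
})

test_that("compiled kernels agree with the double-precision reference", {
  model <- buildCNN(seed = 3)
  set.seed(4)
  X <- matrix(rnorm(2500 * 8), 2500, 8)
  ref <- hsinerve:::cnnForward(model@arch, model@params, X)$logits
  fast <- hsinerve:::.cnnForwardCpp(model@arch$layers, model@params, X)
  expect_equal(fast, ref, tolerance = 1e-3)
})

test_that("analytic gradients match numerical differentiation", {
  model <- buildCNN(seed = 5)
  set.seed(6)
  X <- matrix(rnorm(2500 * 4), 2500, 4)
  y <- c(1L, 3L, 5L, 7L)
  w <- computeClassWeights(setNames(c(5, 10, 20, 5, 8, 40, 12), classLabels(tissueClasses())))
  lossAt <- function(params) {
    fw <- hsinerve:::cnnForward(model@arch, params, X)
    hsinerve:::weightedCrossEntropy(fw$logits, y, w)$loss
  }
  fw <- hsinerve:::cnnForward(model@arch, model@params, X, keepActs = TRUE)
  ce <- hsinerve:::weightedCrossEntropy(fw$logits, y, w)
  gr <- hsinerve:::cnnBackward(model@arch, model@params, X, fw$acts, ce$dLogits)
  eps <- 1e-6
  set.seed(7)
  for (li in c(1L, 4L, 7L, 8L)) {
    for (rep in 1:3) {
      i <- sample(length(model@params[[li]]$W), 1)
      p <- model@params
      p[[li]]$W[i] <- p[[li]]$W[i] + eps; up <- lossAt(p)
      p[[li]]$W[i] <- p[[li]]$W[i] - 2 * eps; dn <- lossAt(p)
      num <- (up - dn) / (2 * eps)
      expect_equal(gr[[li]]$W[i], num, tolerance = 1e-4)
    }
  }
})

test_that("the minibatch loss equals hand-computed weighted cross-entropy", {
  set.seed(8)
  logits <- matrix(rnorm(7 * 4), 7, 4)
  y <- c(2L, 2L, 6L, 1L)
  w <- computeClassWeights(setNames(c(10, 20, 40, 10, 5, 80, 15),
                                    classLabels(tissueClasses())))
  got <- hsinerve:::weightedCrossEntropy(logits, y, w)$loss
  # direct computation: sum_i w_{y_i} * (-log softmax_i[y_i]) / sum_i w_{y_i}
  byHand <- 0; sw <- 0
  for (i in 1:4) {
    p <- exp(logits[, i]) / sum(exp(logits[, i]))
    byHand <- byHand + w[y[i]] * -log(p[y[i]])
    sw <- sw + w[y[i]]
  }
  expect_equal(got, unname(byHand / sw), tolerance = 1e-12)
})

test_that("class weights are inversely proportional to counts, summing to K", {
  equal <- computeClassWeights(setNames(rep(25, 7), classLabels(tissueClasses())))
  expect_equal(unname(equal), rep(1, 7))
  w <- computeClassWeights(c(a = 10, b = 20, c = 40))
  expect_equal(unname(w / w[3]), c(4, 2, 1))
  expect_equal(sum(w), 3)
  w2 <- computeClassWeights(c(a = 100, b = 300))
  expect_equal(unname(w2[1] / w2[2]), 3)
  expect_error(computeClassWeights(c(a = 5, b = 0)), "absent")
})

test_that("training is seeded-deterministic and zero epochs is the identity", {
  cohort <- smallCohort(2, seed = 12)
  ds <- buildDataset(cohort, 5L, "none")
  model <- buildCNN(seed = 9)
  m0 <- trainCNN(model, ds, epochs = 0L, seed = 1)
  expect_identical(m0@params, model@params)
  expect_false(m0@trained)

  m1 <- trainCNN(model, ds, epochs = 2L, seed = 13)
  m2 <- trainCNN(model, ds, epochs = 2L, seed = 13)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@log$loss, m2@log$loss)
  # a different shuffling seed changes the trajectory
  m3 <- trainCNN(model, ds, epochs = 2L, seed = 14)
  expect_false(identical(m1@params, m3@params))
  # loss decreases over a longer run
  m4 <- trainCNN(model, ds, epochs = 8L, seed = 13)
  expect_lt(tail(m4@log$loss, 1), m4@log$loss[1])
})

test_that("normalization provenance is enforced at training and inference", {
  cohort <- smallCohort(2, seed = 15)
  dsRaw <- buildDataset(cohort, 5L, "none")
  dsSnv <- buildDataset(cohort, 5L, "snv")
  model <- buildCNN(normalization = "snv", seed = 10)
  expect_error(trainCNN(model, dsRaw, epochs = 1L), "normalization")
  trained <- trainCNN(model, dsSnv, epochs = 1L)
  expect_error(predictScores(trained, dsRaw), "normalization")
  expect_silent(predictScores(trained, dsSnv))
})

test_that("a missing class in the training data is an error", {
  cohort <- smallCohort(2, seed = 16)
  ds <- buildDataset(cohort, 5L, "none")
  noNerve <- hsinerve:::subsetDataset(ds, ds@labels != 5L)
  expect_error(trainCNN(buildCNN(seed = 1), noNerve, epochs = 1L), "nerve")
})
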