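test_that("LOPOCV folds each hold out exactly one subject", {
  folds <- lopocvSplit(sprintf("S%02d", 1:8))
  expect_length(folds, 8L)
  for (f in folds) {
    expect_false(f$test %in% f$train)
    expect_length(f$train, 7L)
  }
  expect_identical(sort(vapply(folds, `[[`, character(1), "test")),
                   sprintf("S%02d", 1:8))

  f3 <- lopocvSplit(c("A", "B", "C"))
  expect_identical(f3[[1]], list(train = c("B", "C"), test = "A"))
  expect_identical(f3[[2]], list(train = c("A", "C"), test = "B"))
  expect_identical(f3[[3]], list(train = c("A", "B"), test = "C"))

  expect_error(lopocvSplit("only"), "at least 2")
  expect_error(lopocvSplit(c("A", "A", "B")), "duplicate")
})

test_that("confusion matrices count correctly and row-normalize to 1", {
  perfect <- confusionMatrix(1:7, 1:7)
  expect_identical(unname(diag(perfect$normalized)), rep(1, 7))
  expect_identical(sum(perfect$counts), 7L)

  cm <- confusionMatrix(c(1L, 1L, 2L), c(1L, 2L, 2L))
  expect_equal(unname(cm$normalized[1, 1:2]), c(0.5, 0.5))
  expect_equal(unname(cm$normalized[2, 1:2]), c(0, 1))
  expect_true("metal" %in% cm$zeroSupport)

  expect_error(confusionMatrix(c(1L, 9L), c(1L, 1L)), "outside")
  expect_error(confusionMatrix(integer(), integer()), "nonempty")
})

test_that("normalized-confusion rows sum to 1 and diagonals equal sensitivity", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    truth <- sample(1:7, n, replace = TRUE)
    pred <- sample(1:7, n, replace = TRUE)
    cm <- confusionMatrix(truth, pred)
    sums <- rowSums(cm$normalized)
    present <- setdiff(classLabels(tissueClasses()), cm$zeroSupport)
    expect_equal(unname(sums[present]), rep(1, length(present)), tolerance = 1e-12)
    for (code in unique(truth)) {
      m <- oneVsAllMetrics(truth, pred, code)
      expect_equal(unname(diag(cm$normalized)[code]), unname(m["sensitivity"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("one-vs-all metrics match their defining formulas", {
  perfect <- oneVsAllMetrics(c(1L, 2L, 1L), c(1L, 2L, 1L), 1L)
  expect_equal(unname(perfect), c(1, 1, 1))

  # TP=3, FN=1, FP=2, TN=4
  truth <- c(rep(1L, 4), rep(2L, 6))
  pred <- c(1L, 1L, 1L, 2L, 1L, 1L, 2L, 2L, 2L, 2L)
  m <- oneVsAllMetrics(truth, pred, 1L)
  expect_equal(unname(m), c(0.75, 4 / 6, 2 * 3 / (2 * 3 + 2 + 1)), tolerance = 1e-12)

  # DSC equals the harmonic mean of precision and sensitivity
  set.seed(21)
  for (i in 1:30) {
    truth <- sample(1:3, 40, replace = TRUE)
    pred <- sample(1:3, 40, replace = TRUE)
    m <- oneVsAllMetrics(truth, pred, 2L)
    tp <- sum(truth == 2 & pred == 2)
    if (tp == 0) next
    prec <- tp / sum(pred == 2)
    sens <- m[["sensitivity"]]
    expect_equal(m[["dsc"]], 2 * prec * sens / (prec + sens), tolerance = 1e-12)
  }

  # zero support: sensitivity NA, not 0
  m0 <- oneVsAllMetrics(c(2L, 2L), c(2L, 3L), 1L)
  expect_true(is.na(m0[["sensitivity"]]))
})

test_that("macro averaging skips undefined classes", {
  expect_identical(macroAverage(c(1, 1, 1)), 1)
  expect_identical(macroAverage(c(0.5, 1.0)), 0.75)
  expect_identical(macroAverage(c(0.5, NA, 1.0)), 0.75)
  expect_error(macroAverage(c(NA_real_, NA_real_)), "no class")

  # macro sensitivity equals the mean normalized-confusion diagonal when all
  # classes are present
  set.seed(22)
  truth <- rep(1:7, each = 10)
  pred <- sample(1:7, 70, replace = TRUE)
  cm <- confusionMatrix(truth, pred)
  sens <- vapply(1:7, function(k) oneVsAllMetrics(truth, pred, k)[["sensitivity"]],
                 numeric(1))
  expect_equal(macroAverage(sens), mean(diag(cm$normalized)), tolerance = 1e-12)
})

bruteForceAUC <- function(labels, scores) {
  pos <- scores[labels]; neg <- scores[!labels]
  grid <- outer(pos, neg, `-`)
  (sum(grid > 0) + 0.5 * sum(grid == 0)) / length(grid)
}

test_that("ROC curves are monotone and the trapezoidal AUC matches brute force", {
  perfect <- rocCurve(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$auc, 1.0)
  flat <- rocCurve(c(TRUE, FALSE, TRUE, FALSE), rep(0.5, 4))
  expect_equal(flat$auc, 0.5)
  ex <- rocCurve(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.4, 0.5, 0.1))
  expect_equal(ex$auc, 0.75)

  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    r <- rocCurve(labels, scores)
    expect_equal(r$auc, bruteForceAUC(labels, scores), tolerance = 1e-12)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    expect_true(all(r$fpr >= 0 & r$fpr <= 1 & r$tpr >= 0 & r$tpr <= 1))
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))
  }

  expect_error(rocCurve(c(TRUE, TRUE), c(0.1, 0.2)), "both positive and negative")
})

test_that("the paired t-test matches the textbook formula and stats::t.test", {
  tt <- pairedTTest(c(0.1, 0.2, 0.0), c(0, 0, 0))
  expect_equal(tt$t, sqrt(3), tolerance = 1e-4)
  expect_identical(tt$df, 2L)
  expect_equal(tt$p, 0.2254, tolerance = 1e-4)

  set.seed(24)
  a <- runif(8); b <- runif(8)
  mine <- pairedTTest(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  swapped <- pairedTTest(b, a)
  expect_equal(swapped$t, -mine$t)
  expect_equal(swapped$p, mine$p)

  degen <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p))
  expect_error(pairedTTest(1, c(1, 2)), "equal length")
})

test_that("error maps are black on agreement and colored by the wrong class", {
  labels <- matrix(0L, 5, 5)
  labels[2, 2] <- 5L; labels[3, 3] <- 4L
  mask <- AnnotationMask(labels)

  img <- errorMap(mask, labels)
  expect_identical(unname(img), array(0, dim = c(5, 5, 3)))

  pred <- labels
  pred[2, 2] <- 4L   # nerve pixel predicted muscle
  img2 <- errorMap(mask, pred)
  muscleRGB <- as.numeric(grDevices::col2rgb(classColors(tissueClasses())["muscle"]) / 255)
  expect_equal(as.numeric(img2[2, 2, ]), muscleRGB)
  expect_identical(sum(img2 != 0), sum(muscleRGB != 0))

  # unlabeled pixels stay black whatever the prediction
  predAll <- matrix(3L, 5, 5); predAll[2, 2] <- 5L; predAll[3, 3] <- 4L
  expect_identical(sum(errorMap(mask, predAll) != 0), 0L)

  expect_error(errorMap(mask, matrix(0L, 3, 3)), "dimensions")
})
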