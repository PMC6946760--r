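makeLabelledFm <- function(X, y) {
  info <- data.frame(block = "T", feature = "f",
                     index = sprintf("c%03d", seq_len(ncol(X))))
  EMGFeatureMatrix(X, info, labels = y)
}

twoBlobs <- function(n = 200, d = 2, sep = 8, seed = 7) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * d), ncol = d),
             matrix(rnorm(n * d, mean = sep), ncol = d))
  list(X = X, y = rep(c("a", "b"), each = n))
}

test_that("MLE separates well-spaced Gaussian classes", {
  set.seed(7)
  Xtr <- matrix(c(rnorm(200, 0), rnorm(200, 10)), ncol = 1)
  ytr <- rep(c("lo", "hi"), each = 200)
  Xte <- matrix(c(rnorm(200, 0), rnorm(200, 10)), ncol = 1)
  model <- trainClassifier("MLE", makeLabelledFm(Xtr, ytr))
  pred <- predictLabels(model, makeLabelledFm(Xte, ytr))
  expect_gte(mean(pred == ytr) * 100, 99)
})

test_that("LDA and SVM reach 100% on linearly separable blobs", {
  blobs <- twoBlobs()
  fm <- makeLabelledFm(blobs$X, blobs$y)
  cfg <- classifierConfig(svmCostGrid = 2^c(-1, 3), svmGammaGrid = 2^c(-3, 0))
  for (kind in c("LDA", "SVM")) {
    model <- trainClassifier(kind, fm, cfg)
    expect_equal(mean(predictLabels(model, fm) == blobs$y), 1)
  }
})

test_that("KNN with k = 2 self-classifies distinct training points", {
  blobs <- twoBlobs(n = 50, sep = 3)
  fm <- makeLabelledFm(blobs$X, blobs$y)
  model <- trainClassifier("KNN", fm)
  expect_equal(mean(predictLabels(model, fm) == blobs$y), 1)
})

test_that("an unpruned decision tree memorises distinct training rows", {
  set.seed(8)
  X <- matrix(rnorm(60 * 3), ncol = 3)
  y <- sample(c("a", "b", "c"), 60, TRUE)
  fm <- makeLabelledFm(X, y)
  model <- trainClassifier("DT", fm)
  expect_equal(mean(predictLabels(model, fm) == y), 1)
})

test_that("the MLP learns separable blobs and is seed-deterministic", {
  blobs <- twoBlobs(sep = 6)
  fm <- makeLabelledFm(blobs$X, blobs$y)
  m1 <- trainClassifier("MLP", fm, classifierConfig(seed = 3))
  m2 <- trainClassifier("MLP", fm, classifierConfig(seed = 3))
  p1 <- predictLabels(m1, fm)
  expect_identical(p1, predictLabels(m2, fm))
  expect_gte(mean(p1 == blobs$y) * 100, 99)
})

test_that("single-class training yields a constant predictor", {
  X <- matrix(rnorm(20), ncol = 2)
  fm <- makeLabelledFm(X, rep("rest", 10))
  for (kind in c("LDA", "MLE", "KNN")) {
    model <- trainClassifier(kind, fm)
    expect_equal(unique(predictLabels(model, fm)), "rest")
  }
})

test_that("prediction rejects a mismatched feature layout", {
  blobs <- twoBlobs(n = 20)
  fm <- makeLabelledFm(blobs$X, blobs$y)
  model <- trainClassifier("LDA", fm)
  other <- EMGFeatureMatrix(blobs$X,
                            data.frame(block = "U", feature = "g",
                                       index = c("c1", "c2")), blobs$y)
  expect_error(predictLabels(model, other), "column layout")
})

test_that("MLE predictions equal a brute-force Gaussian density argmax", {
  set.seed(9)
  X <- rbind(matrix(rnorm(80, 0), ncol = 2),
             matrix(rnorm(80, 2.5), ncol = 2))
  y <- rep(c("a", "b"), each = 40)
  fm <- makeLabelledFm(X, y)
  model <- trainClassifier("MLE", fm)
  pred <- predictLabels(model, fm)
  # independent oracle: explicit multivariate normal density per class
  dens <- vapply(c("a", "b"), function(cl) {
    Xc <- X[y == cl, ]
    mu <- colMeans(Xc); S <- stats::cov(Xc); Si <- solve(S)
    apply(X, 1, function(r)
      exp(-0.5 * t(r - mu) %*% Si %*% (r - mu)) /
        sqrt((2 * pi)^2 * det(S)))
  }, numeric(nrow(X)))
  expect_equal(pred, c("a", "b")[max.col(dens)])
})

test_that("class-wise accuracy follows the one-vs-rest definition", {
  expect_equal(classwiseAccuracy(diag(c(1, 1))), 100)
  # per class: TP = 50, TN = 40, FP = 5, FN = 5 -> 90%
  cm <- matrix(c(50, 5, 5, 40), 2, byrow = TRUE)
  expect_equal(classwiseAccuracy(cm), 90)
  expect_equal(classwiseAccuracy(matrix(c(0, 3, 3, 0), 2)), 0)
})

test_that("mean recall averages the diagonal of the row-normalised matrix", {
  expect_equal(meanRecall(diag(5)), 100)
  cm <- matrix(c(8, 2, 5, 5), 2, byrow = TRUE)
  expect_equal(meanRecall(cm), mean(c(80, 50)))
  pm <- performanceMatrix(cm)
  expect_equal(rowSums(pm), c(100, 100), ignore_attr = TRUE)
  expect_equal(meanRecall(pm, normalized = TRUE), mean(c(80, 50)))
})

test_that("published performance matrices reproduce their printed averages", {
  files <- c(fs_mle = "performance_fs_mle.csv",
             fe_knn = "performance_fe_knn.csv",
             logrms_mlp = "performance_logrms_mlp.csv")
  expected <- c(fs_mle = 97.43, fe_knn = 90.0, logrms_mlp = 95.47)
  for (nm in names(files)) {
    m <- as.matrix(read.csv(system.file("extdata", files[[nm]],
                                        package = "emgmpr"), row.names = 1))
    expect_equal(meanRecall(m, normalized = TRUE), expected[[nm]],
                 tolerance = 0.0002)
  }
})

test_that("confusion rows sum to the per-class test counts", {
  truth <- rep(c("a", "b", "c"), times = c(5, 3, 2))
  pred <- c("a", "a", "b", "a", "c", "b", "b", "a", "c", "c")
  cm <- confusionCounts(truth, pred)
  expect_equal(rowSums(cm), c(a = 5, b = 3, c = 2))
  expect_equal(sum(cm), 10)
  pm <- performanceMatrix(cm)
  expect_equal(unname(rowSums(pm)), rep(100, 3), tolerance = 1e-9)
})

test_that("cross-validation is deterministic and tracks timings", {
  blobs <- twoBlobs(n = 60, sep = 4)
  fm <- makeLabelledFm(blobs$X, blobs$y)
  ev1 <- crossValidate(fm, "MLE", folds = 5, seed = 11)
  ev2 <- crossValidate(fm, "MLE", folds = 5, seed = 11)
  expect_identical(ev1@perSubject$meanRecall, ev2@perSubject$meanRecall)
  expect_identical(ev1@confusion, ev2@confusion)
  expect_gte(ev1@trainTime, 0)
  expect_gte(ev1@testTime, 0)
  # duplicated subjects produce identical per-subject accuracies
  ev3 <- crossValidate(list(s1 = fm, s2 = fm), "MLE", folds = 5, seed = 11)
  expect_equal(ev3@perSubject$meanRecall[1], ev3@perSubject$meanRecall[2])
})

test_that("label permutation drives accuracy to chance", {
  set.seed(12)
  X <- matrix(rnorm(330 * 4), ncol = 4)
  y <- sample(rep(paste0("m", 1:11), each = 30))
  ev <- suppressWarnings(crossValidate(makeLabelledFm(X, y), "MLE",
                                       folds = 10, seed = 13))
  expect_lt(abs(ev@meanRecall - 100 / 11), 3)
})
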