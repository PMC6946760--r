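# Classifiers, cross-validation, accuracy statistics and the timing harness.
#
# Six classifier kinds: LDA (shared-covariance Gaussian discriminant via
# MASS), KNN (k = 2, Euclidean, ties broken by the nearer neighbour), DT
# (Gini decision tree via rpart, no depth limit), MLE (per-class Gaussian
# with full covariance and equal priors), SVM (RBF kernel via e1071 with an
# inner-CV grid search over cost and gamma) and MLP (two 16-neuron tanh
# hidden layers, softmax output).

CLASSIFIER_KINDS <- c("LDA", "KNN", "DT", "MLE", "SVM", "MLP")

#' Classifier configuration
#'
#' @param knnK neighbours for KNN (default 2; ties go to the nearer
#'   neighbour, which makes k = 2 well defined).
#' @param svmCostGrid,svmGammaGrid RBF-SVM grid-search values (defaults
#'   `2^seq(-5, 15, 2)` and `2^seq(-15, 3, 2)`).
#' @param svmInnerFolds folds of the inner grid-search CV (default 3).
#' @param mlpHidden hidden-layer sizes (default `c(16, 16)`).
#' @param mlpLearningRate,mlpMomentum gradient-descent parameters
#'   (defaults 0.1 and 0.1).
#' @param mlpWeightDecay L2 penalty (default 1e-3).
#' @param mlpMaxEpochs training epoch cap (default 400).
#' @param scale z-score features (training statistics) for KNN, SVM and MLP
#'   (default TRUE).
#' @param seed seed for every stochastic component (MLP init, grid-search
#'   folds).
#' @return A `classifierConfig` list.
#' @export
classifierConfig <- function(knnK = 2L,
                             svmCostGrid = 2^seq(-5, 15, 2),
                             svmGammaGrid = 2^seq(-15, 3, 2),
                             svmInnerFolds = 3L,
                             mlpHidden = c(16L, 16L),
                             mlpLearningRate = 0.1, mlpMomentum = 0.1,
                             mlpWeightDecay = 1e-3, mlpMaxEpochs = 400L,
                             scale = TRUE, seed = 1L) {
  structure(list(knnK = as.integer(knnK), svmCostGrid = svmCostGrid,
                 svmGammaGrid = svmGammaGrid,
                 svmInnerFolds = as.integer(svmInnerFolds),
                 mlpHidden = as.integer(mlpHidden),
                 mlpLearningRate = mlpLearningRate,
                 mlpMomentum = mlpMomentum,
                 mlpWeightDecay = mlpWeightDecay,
                 mlpMaxEpochs = as.integer(mlpMaxEpochs),
                 scale = scale, seed = as.integer(seed)),
            class = "classifierConfig")
}

standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

applyStandardizer <- function(std, X) {
  sweep(sweep(X, 2L, std$center), 2L, std$scale, "/")
}

ridgeCovariance <- function(X) {
  S <- stats::cov(X)
  d <- ncol(S)
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) {
    warning("singular class covariance; ridge added", call. = FALSE)
    S <- S + diag(1e-6 * sum(diag(S)) / d + 1e-12, d)
  }
  S
}

gaussianLogDensity <- function(X, mu, S) {
  R <- chol(S)
  D <- forwardsolve(t(R), t(X) - mu)
  -0.5 * colSums(D^2) - sum(log(diag(R))) - 0.5 * ncol(X) * log(2 * pi)
}

stratifiedFolds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    if (length(idx) < folds)
      warning("class '", cl, "' has fewer windows than folds; ",
              "stratification degrades to best effort", call. = FALSE)
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

svmGridSearch <- function(X, y, cfg) {
  fold <- stratifiedFolds(as.character(y), cfg$svmInnerFolds, cfg$seed + 7L)
  best <- c(acc = -1, cost = NA, gamma = NA)
  for (cost in cfg$svmCostGrid) for (gamma in cfg$svmGammaGrid) {
    hits <- 0L
    for (f in seq_len(cfg$svmInnerFolds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
      hits <- hits + sum(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
    }
    if (hits > best["acc"]) best <- c(acc = hits, cost = cost, gamma = gamma)
  }
  best
}

#' Train a movement classifier
#'
#' @param kind one of `"LDA"`, `"KNN"`, `"DT"`, `"MLE"`, `"SVM"`, `"MLP"`.
#' @param fm an [EMGFeatureMatrix-class] of training windows.
#' @param config a [classifierConfig()].
#' @return A `trainedModel` usable with [predictLabels()]; it predicts only
#'   labels seen during training.
#' @export
trainClassifier <- function(kind, fm, config = classifierConfig()) {
  kind <- match.arg(toupper(kind), CLASSIFIER_KINDS)
  X <- featureValues(fm)
  y <- factor(windowLabels(fm))
  if (nlevels(y) < 2L) {
    # degenerate single-class training set: constant predictor
    return(structure(list(kind = kind, constant = levels(y),
                          columns = featureIds(featureInfo(fm))),
                     class = "trainedModel"))
  }
  std <- NULL
  if (config$scale && kind %in% c("KNN", "SVM", "MLP")) {
    std <- standardizer(X)
    X <- applyStandardizer(std, X)
  }
  fit <- switch(kind,
    LDA = MASS::lda(X, grouping = y),
    KNN = list(X = X, y = y, k = config$knnK),
    DT = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = 2L,
                                                  minbucket = 1L, cp = 0,
                                                  xval = 0L))
    },
    MLE = lapply(levels(y), function(cl) {
      Xc <- X[y == cl, , drop = FALSE]
      list(mu = colMeans(Xc), S = ridgeCovariance(Xc))
    }),
    SVM = {
      grid <- svmGridSearch(X, y, config)
      e1071::svm(X, y, kernel = "radial", cost = grid[["cost"]],
                 gamma = grid[["gamma"]], scale = FALSE)
    },
    MLP = {
      Y <- diag(nlevels(y))[as.integer(y), , drop = FALSE]
      mlpTrain(X, Y, hidden = config$mlpHidden,
               learningRate = config$mlpLearningRate,
               momentum = config$mlpMomentum,
               weightDecay = config$mlpWeightDecay,
               maxEpochs = config$mlpMaxEpochs, seed = config$seed)
    })
  structure(list(kind = kind, fit = fit, levels = levels(y), std = std,
                 columns = featureIds(featureInfo(fm))),
            class = "trainedModel")
}

#' Predict movement labels
#'
#' @param model a `trainedModel` from [trainClassifier()].
#' @param fm an [EMGFeatureMatrix-class] with the training column layout.
#' @return Character vector of predicted labels, one per window.
#' @export
predictLabels <- function(model, fm) {
  cols <- featureIds(featureInfo(fm))
  if (!identical(cols, model$columns))
    stop("feature column layout differs from the training data")
  X <- featureValues(fm)
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
  if (!is.null(model$std)) X <- applyStandardizer(model$std, X)
  out <- switch(model$kind,
    LDA = as.character(predict(model$fit, X)$class),
    KNN = knnPredict(model$fit, X),
    DT = {
      df <- data.frame(X, check.names = FALSE)
      as.character(predict(model$fit, df, type = "class"))
    },
    MLE = {
      ll <- vapply(model$fit,
                   function(p) gaussianLogDensity(X, p$mu, p$S),
                   numeric(nrow(X)))
      ll <- matrix(ll, nrow = nrow(X))
      model$levels[max.col(ll, ties.method = "first")]
    },
    SVM = as.character(predict(model$fit, X)),
    MLP = {
      P <- mlpPredict(model$fit, X)
      model$levels[max.col(P, ties.method = "first")]
    })
  out
}

# k-nearest neighbours with nearer-neighbour tie-break (for k = 2 this
# reduces to the nearest neighbour, making k = 2 well defined)
knnPredict <- function(fit, X) {
  trn <- fit$X; y <- as.character(fit$y); k <- fit$k
  d2 <- outer(rowSums(X^2), rep(1, nrow(trn))) +
    outer(rep(1, nrow(X)), rowSums(trn^2)) - 2 * X %*% t(trn)
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    ord <- order(d2[i, ])[seq_len(min(k, ncol(d2)))]
    votes <- table(y[ord])
    top <- names(votes)[votes == max(votes)]
    out[i] <- if (length(top) == 1L) top else y[ord[1L]]
  }
  out
}

#' Confusion matrix and accuracy statistics
#'
#' `confusionCounts` tabulates intended (rows) versus detected (columns)
#' movements.  `classwiseAccuracy` is the one-vs-rest accuracy
#' `(TP + TN) / (TP + TN + FP + FN)` averaged over classes, in percent.
#' `meanRecall` is the mean of the diagonal of the row-normalised percent
#' matrix -- the statistic printed under published performance matrices.
#' `performanceMatrix` returns that row-normalised percent matrix.
#'
#' @param truth,predicted label vectors of equal length.
#' @param classes optional fixed class ordering.
#' @param cm a square counts (or percent, for `meanRecall`) matrix with
#'   intended movements in rows.
#' @return `confusionCounts`: integer matrix; the statistics: scalars (%).
#' @export
confusionCounts <- function(truth, predicted,
                            classes = sort(unique(c(truth, predicted)))) {
  t1 <- factor(truth, levels = classes)
  p1 <- factor(predicted, levels = classes)
  tab <- table(intended = t1, detected = p1)
  matrix(as.integer(tab), nrow = length(classes),
         dimnames = list(intended = classes, detected = classes))
}

#' @rdname confusionCounts
#' @export
classwiseAccuracy <- function(cm) {
  n <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  mean((tp + tn) / (tp + tn + fp + fn)) * 100
}

#' @rdname confusionCounts
#' @param normalized set TRUE when `cm` is already a row-normalised percent
#'   matrix (e.g. a published performance matrix), in which case the mean of
#'   its diagonal is returned as-is.
#' @export
meanRecall <- function(cm, normalized = FALSE) {
  if (normalized) return(mean(diag(cm)))
  rs <- rowSums(cm)
  keep <- rs > 0
  if (!all(keep))
    warning("class(es) without test windows excluded from mean recall",
            call. = FALSE)
  mean(diag(cm)[keep] / rs[keep]) * 100
}

#' @rdname confusionCounts
#' @export
performanceMatrix <- function(cm) {
  rs <- rowSums(cm)
  rs[rs == 0] <- 1
  sweep(cm, 1L, rs, "/") * 100
}

#' Cross-validated evaluation
#'
#' Stratified random 10-fold cross-validation within each subject; fold
#' accuracies are averaged per subject and then across subjects.  Wall-clock
#' training and prediction times are accumulated per the timing protocol
#' (absolute values are hardware dependent and reported for comparison
#' only).
#'
#' @param fms an [EMGFeatureMatrix-class] or a named list of them (one per
#'   subject).
#' @param kind classifier kind (see [trainClassifier()]).
#' @param folds number of folds (default 10).
#' @param seed seed controlling fold assignment and all stochastic
#'   components; equal seeds give identical reports.
#' @param config a [classifierConfig()].
#' @return An `EMGEvaluation` object: mean/sd of the class-wise accuracy and
#'   of the mean recall across subjects, the pooled performance matrix
#'   (percent, intended movements in rows), and summed train/test times in
#'   seconds.
#' @export
crossValidate <- function(fms, kind, folds = 10L, seed = 1L,
                          config = classifierConfig(seed = seed)) {
  if (is(fms, "EMGFeatureMatrix")) fms <- list(subject = fms)
  classes <- sort(unique(unlist(lapply(fms, windowLabels))))
  perSubject <- data.frame(subject = character(), meanRecall = numeric(),
                           classwiseAccuracy = numeric())
  pooled <- matrix(0, length(classes), length(classes),
                   dimnames = list(intended = classes, detected = classes))
  trainTime <- 0; testTime <- 0
  for (si in seq_along(fms)) {
    fm <- fms[[si]]
    labels <- as.character(windowLabels(fm))
    if (length(labels) < folds) stop("fewer windows than folds")
    fold <- stratifiedFolds(labels, folds, seed)
    cmSubject <- matrix(0, length(classes), length(classes),
                        dimnames = dimnames(pooled))
    foldRecall <- foldAcc <- numeric(0)
    for (f in seq_len(folds)) {
      trIdx <- which(fold != f); teIdx <- which(fold == f)
      if (length(teIdx) == 0L) next
      tr <- fm[, trIdx]; te <- fm[, teIdx]
      t0 <- proc.time()[["elapsed"]]
      model <- trainClassifier(kind, tr, config)
      t1 <- proc.time()[["elapsed"]]
      pred <- predictLabels(model, te)
      t2 <- proc.time()[["elapsed"]]
      trainTime <- trainTime + (t1 - t0)
      testTime <- testTime + (t2 - t1)
      cm <- confusionCounts(labels[teIdx], pred, classes)
      cmSubject <- cmSubject + cm
      foldRecall <- c(foldRecall, suppressWarnings(meanRecall(cm)))
      foldAcc <- c(foldAcc, classwiseAccuracy(cm))
    }
    pooled <- pooled + cmSubject
    perSubject <- rbind(perSubject, data.frame(
      subject = names(fms)[si] %||% as.character(si),
      meanRecall = mean(foldRecall), classwiseAccuracy = mean(foldAcc)))
  }
  new("EMGEvaluation", kind = kind, folds = as.integer(folds),
      seed = as.integer(seed), perSubject = perSubject,
      meanRecall = mean(perSubject$meanRecall),
      sdRecall = if (nrow(perSubject) > 1L) sd(perSubject$meanRecall) else 0,
      meanClasswiseAccuracy = mean(perSubject$classwiseAccuracy),
      sdClasswiseAccuracy = if (nrow(perSubject) > 1L)
        sd(perSubject$classwiseAccuracy) else 0,
      confusion = pooled,
      performance = performanceMatrix(pooled),
      trainTime = trainTime, testTime = testTime)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Cross-validated evaluation report
#'
#' @slot kind classifier kind.
#' @slot folds,seed evaluation settings.
#' @slot perSubject per-subject accuracies.
#' @slot meanRecall,sdRecall mean/sd across subjects of the mean per-class
#'   recall (%).
#' @slot meanClasswiseAccuracy,sdClasswiseAccuracy mean/sd of the one-vs-rest
#'   class-wise accuracy (%).
#' @slot confusion pooled counts (intended x detected).
#' @slot performance pooled row-normalised percent matrix.
#' @slot trainTime,testTime accumulated wall-clock seconds.
#' @export
setClass("EMGEvaluation",
  representation(kind = "character", folds = "integer", seed = "integer",
                 perSubject = "data.frame", meanRecall = "numeric",
                 sdRecall = "numeric", meanClasswiseAccuracy = "numeric",
                 sdClasswiseAccuracy = "numeric", confusion = "matrix",
                 performance = "matrix", trainTime = "numeric",
                 testTime = "numeric"))

setMethod("show", "EMGEvaluation", function(object) {
  cat(sprintf("EMGEvaluation: %s, %d-fold CV, %d subject(s)\n", object@kind,
              object@folds, nrow(object@perSubject)))
  cat(sprintf("  mean recall:          %.2f%% (sd %.2f)\n",
              object@meanRecall, object@sdRecall))
  cat(sprintf("  class-wise accuracy:  %.2f%% (sd %.2f)\n",
              object@meanClasswiseAccuracy, object@sdClasswiseAccuracy))
  cat(sprintf("  train/test time:      %.3f s / %.3f s\n",
              object@trainTime, object@testTime))
})

#' Write an evaluation report to disk
#'
#' Writes `report.json` (summary statistics and timings) and
#' `performance_matrix.csv` (row-normalised percentages, intended movements
#' in rows, two decimals).
#'
#' @param ev an `EMGEvaluation`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(ev, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(kind = ev@kind, folds = ev@folds, seed = ev@seed,
                  meanRecall = ev@meanRecall, sdRecall = ev@sdRecall,
                  meanClasswiseAccuracy = ev@meanClasswiseAccuracy,
                  sdClasswiseAccuracy = ev@sdClasswiseAccuracy,
                  trainTimeSec = ev@trainTime, testTimeSec = ev@testTime,
                  perSubject = ev@perSubject)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write.csv(round(ev@performance, 2), file.path(dir, "performance_matrix.csv"))
  invisible(dir)
}
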