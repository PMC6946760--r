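# Dimensionality reduction: z-scored PCA projection to a small number of
# components (default 20), and the two-pass sequential forward-selection /
# backward-elimination wrapper over feature blocks.

#' Fit and apply a PCA projection
#'
#' `pcaFit` standardises every column (z-score; zero-variance columns get
#' scale 1 with a warning) and extracts the top `m` principal axes from the
#' training windows only.  `pcaApply` standardises with the *training*
#' statistics and projects, so no information leaks from held-out folds.
#'
#' @param train an [EMGFeatureMatrix-class] of training windows.
#' @param m number of retained components (default 20).
#' @return `pcaFit`: a `pcaProjection` with `center`, `scale`, `loadings`
#'   (columns orthonormal) and `m`.  `pcaApply`: an
#'   [EMGFeatureMatrix-class] of `m` projected columns.
#' @export
pcaFit <- function(train, m = 20L) {
  X <- featureValues(train)
  if (nrow(X) <= m)
    stop("PCA needs more training windows than retained components")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  if (any(scl == 0)) {
    warning("zero-variance feature column(s); scale 1 substituted")
    scl[scl == 0] <- 1
  }
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  m <- min(m, ncol(X))
  sv <- svd(Z, nu = 0, nv = m)
  structure(list(center = ctr, scale = scl,
                 loadings = sv$v,
                 sdev = sv$d / sqrt(nrow(X) - 1), m = m),
            class = "pcaProjection")
}

#' @rdname pcaFit
#' @param proj a fitted `pcaProjection`.
#' @param fm feature matrix to project (same column layout as `train`).
#' @export
pcaApply <- function(proj, fm) {
  X <- featureValues(fm)
  if (ncol(X) != length(proj$center))
    stop("column layout differs from the PCA training matrix")
  Z <- sweep(sweep(X, 2L, proj$center), 2L, proj$scale, "/")
  scores <- Z %*% proj$loadings
  info <- data.frame(block = "PCA", feature = "PC",
                     index = sprintf("pc%02d", seq_len(proj$m)))
  EMGFeatureMatrix(scores, info, labels = windowLabels(fm),
                   entry = colData(fm)$entry)
}

#' Sequential forward selection with backward elimination
#'
#' Pass 1 walks the candidate blocks in the given order, keeping a block only
#' if adding it strictly increases the evaluated accuracy.  Pass 2 walks the
#' kept blocks in inverted order and removes a block if the accuracy without
#' it is no lower than the current best.  The empty-set baseline is chance
#' accuracy, so the first informative block always enters.
#'
#' @param blocks candidate block names, in evaluation order.
#' @param evaluator function taking a character vector of block names and
#'   returning a cross-validated accuracy (any fixed scale); must be
#'   deterministic for reproducible selection.
#' @param baseline empty-set accuracy (default chance = `100 / nClasses` on
#'   the percent scale).
#' @param nClasses number of classes used for the default baseline.
#' @return List with `blocks` (the selected set), `accuracy` (its evaluated
#'   accuracy) and `trace` (a data.frame logging every evaluation).
#' @export
forwardBackwardSelect <- function(blocks, evaluator, nClasses = 11L,
                                  baseline = 100 / nClasses) {
  stopifnot(length(blocks) >= 1L)
  trace <- data.frame(pass = character(), candidate = character(),
                      accuracy = numeric(), kept = logical())
  current <- character(0)
  best <- baseline
  for (b in blocks) {
    acc <- evaluator(c(current, b))
    keep <- acc > best
    if (keep) { current <- c(current, b); best <- acc }
    trace <- rbind(trace, data.frame(pass = "forward", candidate = b,
                                     accuracy = acc, kept = keep))
  }
  for (b in rev(current)) {
    if (length(current) == 1L) break
    reduced <- setdiff(current, b)
    acc <- evaluator(reduced)
    drop <- acc >= best
    if (drop) { current <- reduced; best <- acc }
    trace <- rbind(trace, data.frame(pass = "backward", candidate = b,
                                     accuracy = acc, kept = !drop))
  }
  if (length(current) == 0L) {
    warning("no block improved on the baseline; returning the best single block")
    fw <- trace[trace$pass == "forward", ]
    current <- fw$candidate[which.max(fw$accuracy)]
    best <- max(fw$accuracy)
  }
  list(blocks = current, accuracy = best, trace = trace)
}
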