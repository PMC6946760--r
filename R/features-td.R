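# The 25 time-domain window features.  Single-channel features take a
# numeric vector `x` (one channel of one analysis window); Cor and the
# multi-channel energy ratio take the full channels x N window matrix.
#
# Degenerate inputs (e.g. constant windows where a variance-normalised
# feature is undefined) return NaN with a warning rather than a silent zero,
# except where zero is the true limit (WL, DAMV, DASDV, ...).

#' Threshold and bin configuration for time-domain features
#'
#' @param sscThreshold slope-sign-change product threshold (default 0).
#' @param wamThreshold Willison amplitude difference threshold (default 0).
#' @param histBins number of histogram bins (default 9).
#' @param fdimKmax largest time-step used by Higuchi's fractal dimension
#'   (default 10).
#' @param fdimK time-step of the standalone FDim feature column
#'   (default `fdimKmax`).
#' @return A `thresholdConfig` list.
#' @export
thresholdConfig <- function(sscThreshold = 0, wamThreshold = 0,
                            histBins = 9L, fdimKmax = 10L, fdimK = fdimKmax) {
  stopifnot(sscThreshold >= 0, wamThreshold >= 0, histBins >= 1, fdimKmax >= 2)
  structure(list(sscThreshold = sscThreshold, wamThreshold = wamThreshold,
                 histBins = as.integer(histBins), fdimKmax = as.integer(fdimKmax),
                 fdimK = as.integer(fdimK)),
            class = "thresholdConfig")
}

sentinel <- function(what) {
  warning(what, " undefined for this window; returning NaN", call. = FALSE)
  NaN
}

#' Time-domain window features
#'
#' Scalar statistics of one channel of one analysis window.  `featMAV` is the
#' mean absolute value, `featSTD` the sample standard deviation, `featVAR`
#' the (uncentred) power `sum(x^2)/(N-1)`, `featWL` the waveform length
#' (summed absolute first differences), `featZC` the zero-crossing count
#' (strict sign changes), `featSSC` the slope-sign-change count with product
#' threshold, `featDAMV` the mean absolute first difference, `featMFL` the
#' maximum fractal length `log10(sqrt(sum(diff(x)^2)))`, `featIAV` the
#' integrated absolute value, `featDASDV` the standard deviation of first
#' differences, `featWAM` the Willison amplitude count, and `featPerc75` the
#' 75th percentile by nearest rank.
#'
#' @param x numeric vector, one channel of one window (mV).
#' @param cfg a [thresholdConfig()] where thresholds are involved.
#' @return A scalar feature value.
#' @name td-features
NULL

#' @rdname td-features
#' @export
featMAV <- function(x) mean(abs(x))

#' @rdname td-features
#' @export
featSTD <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

#' @rdname td-features
#' @export
featVAR <- function(x) sum(x^2) / (length(x) - 1)

#' @rdname td-features
#' @export
featWL <- function(x) sum(abs(diff(x)))

#' @rdname td-features
#' @export
featZC <- function(x) sum(x[-1] * x[-length(x)] < 0)

#' @rdname td-features
#' @export
featSSC <- function(x, cfg = thresholdConfig()) {
  n <- length(x)
  if (n < 3L) stop("SSC needs at least 3 samples")
  mid <- x[2:(n - 1)]
  sum((mid - x[1:(n - 2)]) * (mid - x[3:n]) > cfg$sscThreshold)
}

#' @rdname td-features
#' @export
featDAMV <- function(x) sum(abs(diff(x))) / length(x)

#' @rdname td-features
#' @export
featMFL <- function(x) {
  ss <- sum(diff(x)^2)
  if (ss == 0) return(sentinel("MFL (all-equal samples)"))
  log10(sqrt(ss))
}

#' @rdname td-features
#' @export
featIAV <- function(x) sum(abs(x))

#' @rdname td-features
#' @export
featDASDV <- function(x) sqrt(sum(diff(x)^2) / (length(x) - 1))

#' @rdname td-features
#' @export
featWAM <- function(x, cfg = thresholdConfig()) {
  sum(abs(diff(x)) > cfg$wamThreshold)
}

#' @rdname td-features
#' @export
featPerc75 <- function(x) {
  n <- length(x)
  sorted <- sort(x)
  sorted[min(floor(0.75 * n) + 1L, n)]
}

#' Peak-based features: number, mean and mean firing velocity of peaks
#'
#' Peaks are the raw samples strictly greater than the window RMS.  `NP` is
#' their count, `MPV` their mean (0 when there are none) and `MFV` the mean
#' of successive differences of the peak values (0 when fewer than two
#' peaks).
#'
#' @param x numeric vector, one channel of one window.
#' @return Named numeric vector `c(NP, MPV, MFV)`.
#' @export
featPeaks <- function(x) {
  rms <- sqrt(mean(x^2))
  peaks <- x[x > rms]
  np <- length(peaks)
  c(NP = np,
    MPV = if (np > 0L) mean(peaks) else 0,
    MFV = if (np > 1L) mean(diff(peaks)) else 0)
}

#' Curve length at time-step k and Higuchi's fractal dimension
#'
#' `featFDim` computes the curve length of the window re-sampled at step `k`,
#' scaled by `(N-1)/N` and normalised by `k`.  `featHFD` is the slope of
#' `log10` curve length between steps 1 and `fdimKmax` (default 10), i.e.
#' Higuchi's two-point fractal dimension estimate: ~1 for a smooth line and
#' approaching 2 for rough, noise-like signals.
#'
#' @param x numeric vector, one channel of one window.
#' @param k time-step (1 <= k < length(x)).
#' @param cfg a [thresholdConfig()] supplying `fdimKmax`.
#' @return A scalar.
#' @export
featFDim <- function(x, k = 1L) {
  n <- length(x)
  if (k < 1L || k >= n) stop("time-step k must satisfy 1 <= k < N")
  i <- seq_len((n - 1L) %/% k)          # 0-based X(ik) vs X((i-1)k)
  sum(abs(x[i * k + 1L] - x[(i - 1L) * k + 1L])) * (n - 1) / n / k
}

#' @rdname featFDim
#' @export
featHFD <- function(x, cfg = thresholdConfig()) {
  kmax <- cfg$fdimKmax
  if (length(x) <= kmax) stop("window shorter than fdimKmax")
  f1 <- featFDim(x, 1L)
  fk <- featFDim(x, kmax)
  if (f1 == 0 || fk == 0) return(sentinel("HFD (zero curve length)"))
  (log10(f1) - log10(fk)) / log10(kmax)
}

#' Skewness and kurtosis
#'
#' Population central moments `M_k = mean((x - mean(x))^k)`; skewness is
#' `M3 / M2^1.5`, kurtosis `M4 / M2^2` (no excess correction).
#'
#' @param x numeric vector, one channel of one window.
#' @return A scalar; NaN with a warning when the window is constant.
#' @export
featSkew <- function(x) {
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(sentinel("skewness (constant window)"))
  mean(d^3) / (m2 * sqrt(m2))
}

#' @rdname featSkew
#' @export
featKurt <- function(x) {
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(sentinel("kurtosis (constant window)"))
  mean(d^4) / (m2 * m2)
}

#' Hjorth mobility and complexity
#'
#' Mobility is `sqrt(var(diff(x)) / var(x))` (a spectral-spread proxy);
#' complexity is the mobility of the first difference divided by the mobility
#' of the signal, equal to 1 for a pure sine sampled densely.  Variances here
#' are mean-subtracted sample variances, the traditional Hjorth definition.
#'
#' @param x numeric vector, one channel of one window.
#' @return A scalar; NaN with a warning when a denominator variance is zero.
#' @export
featHjorthMobility <- function(x) {
  v <- var(x)
  if (v == 0) return(sentinel("Hjorth mobility (constant window)"))
  sqrt(var(diff(x)) / v)
}

#' @rdname featHjorthMobility
#' @export
featHjorthComplexity <- function(x) {
  dx <- diff(x)
  v <- var(x); vd <- var(dx)
  if (v == 0 || vd == 0)
    return(sentinel("Hjorth complexity (constant window or ramp)"))
  sqrt(var(diff(dx)) / vd) / sqrt(vd / v)
}

#' Absolute value of the Pearson correlation of two channels
#'
#' @param xa,xb numeric vectors of equal length (two channels of the same
#'   window).
#' @return `|r|` in `[0, 1]`; NaN with a warning for constant input.
#' @export
featCor <- function(xa, xb) {
  da <- xa - mean(xa); db <- xb - mean(xb)
  den <- sqrt(sum(da^2) * sum(db^2))
  if (den == 0) {
    warning("correlation undefined for constant channel; returning 0",
            call. = FALSE)
    return(0)
  }
  abs(sum(da * db)) / den
}

#' Multi-channel energy ratios
#'
#' Channel energies `E_j = sum(x_j^2)`; for channels `j = 2..M-1` and
#' `k = j+1..M` the normalised ratio `ER_jk = E_j * E_1 / E_k^2` is emitted
#' (3 values for 4 channels).
#'
#' @param win channels x N numeric matrix (one window, all channels).
#' @return Named numeric vector of ratios.
#' @export
featEnergyRatio <- function(win) {
  M <- nrow(win)
  if (M < 3L) stop("energy ratio needs at least 3 channels")
  E <- rowSums(win^2)
  out <- numeric(0)
  for (j in 2:(M - 1)) for (k in (j + 1):M) {
    val <- if (E[k] == 0 || E[1] == 0)
      sentinel(sprintf("energy ratio ER_%d%d (zero channel energy)", j, k))
    else E[j] * E[1] / E[k]^2
    out <- c(out, setNames(val, sprintf("ch%d_ch%d", j, k)))
  }
  out
}

#' Mean absolute value slope across a window sequence
#'
#' For the ordered windows of one schedule entry and channel, the forward
#' difference of consecutive MAVs is assigned to each window; the final
#' window gets 0 so every window keeps one value.
#'
#' @param mavs numeric vector of per-window MAVs (in temporal order).
#' @return Numeric vector of the same length.
#' @export
featMAVS <- function(mavs) {
  n <- length(mavs)
  if (n == 1L) return(0)
  c(diff(mavs), 0)
}

#' Amplitude histogram
#'
#' Counts over `histBins` equally spaced bins spanning `[min(x), max(x)]`,
#' the last bin right-closed.  A constant window puts all samples in bin 1.
#'
#' @param x numeric vector, one channel of one window.
#' @param cfg a [thresholdConfig()] supplying `histBins`.
#' @return Integer vector of counts summing to `length(x)`.
#' @export
featHist <- function(x, cfg = thresholdConfig()) {
  nb <- cfg$histBins
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(c(length(x), rep(0L, nb - 1L)))
  idx <- pmin(floor((x - lo) / ((hi - lo) / nb)) + 1L, nb)
  tabulate(idx, nbins = nb)
}
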