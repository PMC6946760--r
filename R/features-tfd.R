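# The 11 time-frequency features: eight statistics of the final-level DWT
# coefficients (4th-order Coiflet) and three wavelet-packet subspace
# features (5th-order Symmlet), per channel.

#' Statistics of final-level DWT coefficients
#'
#' Eight statistics of the concatenated level-4 approximation and detail
#' coefficients: standard deviation, variance (uncentred `sum(c^2)/(n-1)`),
#' waveform length, energy `sum(c^2)`, maximum absolute value, zero-crossing
#' count, mean and mean absolute value.
#'
#' @param dwt result of [dwtDecompose()].
#' @return Named numeric vector of 8 values
#'   (`STD, VAR, WL, ENERGY, MAXAV, ZC, MEAN, MAV`).
#' @export
featDWTStats <- function(dwt) {
  cf <- dwt$combined
  c(STD = featSTD(cf), VAR = featVAR(cf), WL = featWL(cf),
    ENERGY = sum(cf^2), MAXAV = max(abs(cf)), ZC = featZC(cf),
    MEAN = mean(cf), MAV = featMAV(cf))
}

#' Wavelet-packet subspace features
#'
#' For each of the `2^levels` frequency-ordered leaf subspaces:
#' `featLogRMS` is the natural log of the RMS of the subspace coefficients,
#' `featRelativeEnergy` the subspace energy divided by the total energy
#' (summing to 1), and `featNLE` the normalized logarithmic energy
#' `log(sum(c^2) / n_p)` with `n_p = N / 2^levels` coefficients per subspace
#' (exact under periodization), so `NLE = 2 * LogRMS` identically.
#'
#' @param wpt result of [wptDecompose()].
#' @return Named numeric vector, one value per subspace; zero-energy
#'   subspaces yield NaN with a warning (for relative energy, a zero total
#'   energy does).
#' @name wpt-features
NULL

#' @rdname wpt-features
#' @export
featLogRMS <- function(wpt) {
  vapply(wpt$subspaces, function(w) {
    e <- sum(w^2)
    if (e == 0) sentinel("LogRMS (zero-energy subspace)")
    else log(sqrt(e / length(w)))
  }, numeric(1))
}

#' @rdname wpt-features
#' @export
featRelativeEnergy <- function(wpt) {
  if (wpt$totalEnergy == 0) {
    warning("relative energy undefined for an all-zero window; returning NaN",
            call. = FALSE)
    return(setNames(rep(NaN, length(wpt$energies)), names(wpt$energies)))
  }
  wpt$energies / wpt$totalEnergy
}

#' @rdname wpt-features
#' @export
featNLE <- function(wpt) {
  vapply(wpt$subspaces, function(w) {
    e <- sum(w^2)
    if (e == 0) sentinel("NLE (zero-energy subspace)")
    else log(e / length(w))
  }, numeric(1))
}
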