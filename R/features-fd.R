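# The 8 frequency-domain features, computed on the unpadded FFT of each
# window.  Physical statistics (MNF, MDF, FR, PKF, MPK, STDPK) use the
# one-sided spectrum; waveform length and the 10 Hz energy bins use the full
# two-sided FFT array.

#' Frequency-band configuration for the frequency ratio
#'
#' @param lowBand low-frequency band in Hz, half-open `[low, high)`
#'   (default `c(10, 250)`).
#' @param highBand high-frequency band in Hz, closed `[low, high]`
#'   (default `c(250, 500)`).
#' @return A `bandConfig` list.
#' @export
bandConfig <- function(lowBand = c(10, 250), highBand = c(250, 500)) {
  stopifnot(length(lowBand) == 2L, length(highBand) == 2L,
            lowBand[1] < lowBand[2], highBand[1] < highBand[2],
            lowBand[2] <= highBand[1])
  structure(list(lowBand = lowBand, highBand = highBand), class = "bandConfig")
}

#' Window spectrum
#'
#' Unpadded FFT of one channel of one window; frequency resolution is
#' `fs / N` (5 Hz for 400-sample windows at 2000 Hz).  The one-sided view
#' keeps bins 0..floor(N/2) covering 0 to fs/2; the two-sided view keeps all
#' N bins covering 0 to `fs * (N-1) / N`.
#'
#' @param x numeric vector, one channel of one window.
#' @param fs sampling rate (Hz).
#' @param sided `"one"` or `"two"`.
#' @return A `spectrum` list with `mag` (magnitudes), `power` (`mag^2`),
#'   `freqs` (Hz), `deltaF` and `sided`.
#' @export
windowSpectrum <- function(x, fs, sided = c("one", "two")) {
  sided <- match.arg(sided)
  n <- length(x)
  stopifnot(n >= 2L)
  X <- fft(x)
  if (sided == "one") {
    m <- n %/% 2L + 1L
    X <- X[seq_len(m)]
  }
  mag <- Mod(X)
  freqs <- (seq_along(mag) - 1) * fs / n
  structure(list(mag = mag, power = mag^2, freqs = freqs, deltaF = fs / n,
                 sided = sided, n = n, fs = fs),
            class = "emgSpectrum")
}

#' Frequency-domain features
#'
#' `featWLFD` applies the waveform-length sum to the two-sided FFT magnitude;
#' `featMNF` is the power-weighted mean frequency; `featMDF` the median
#' frequency (smallest frequency at which cumulative power reaches half the
#' total); `featSpectralPeaks` returns the mean (`MPK`) and standard
#' deviation (`STDPK`) of the one-sided magnitude bins exceeding the RMS of
#' the magnitude vector; `featFR` the ratio of low-band to high-band power;
#' `featPKF` the frequency of maximum power (ties resolved toward the lowest
#' frequency).
#'
#' @param s an [windowSpectrum()] of the appropriate sidedness.
#' @param bands a [bandConfig()] (for `featFR`).
#' @return A scalar (or named pair for `featSpectralPeaks`).
#' @name fd-features
NULL

#' @rdname fd-features
#' @export
featWLFD <- function(s) {
  stopifnot(s$sided == "two")
  sum(abs(diff(s$mag)))
}

#' @rdname fd-features
#' @export
featMNF <- function(s) {
  stopifnot(s$sided == "one")
  tot <- sum(s$power)
  if (tot == 0) return(sentinel("MNF (zero power)"))
  sum(s$freqs * s$power) / tot
}

#' @rdname fd-features
#' @export
featMDF <- function(s) {
  stopifnot(s$sided == "one")
  tot <- sum(s$power)
  if (tot == 0) return(sentinel("MDF (zero power)"))
  # tiny relative tolerance so an exact half-split resolves to the lower bin
  s$freqs[which(cumsum(s$power) >= tot / 2 * (1 - 1e-9))[1L]]
}

#' @rdname fd-features
#' @export
featSpectralPeaks <- function(s) {
  stopifnot(s$sided == "one")
  rms <- sqrt(mean(s$mag^2))
  peaks <- s$mag[s$mag > rms]
  if (length(peaks) == 0L)
    return(c(MPK = sentinel("spectral peaks (none above RMS)"), STDPK = NaN))
  c(MPK = mean(peaks),
    STDPK = if (length(peaks) > 1L) sd(peaks) else 0)
}

#' @rdname fd-features
#' @export
featFR <- function(s, bands = bandConfig()) {
  stopifnot(s$sided == "one")
  lowIdx <- s$freqs >= bands$lowBand[1] & s$freqs < bands$lowBand[2]
  highIdx <- s$freqs >= bands$highBand[1] & s$freqs <= bands$highBand[2]
  hi <- sum(s$power[highIdx])
  tot <- sum(s$power)
  # an "empty" high band only holds spectral-leakage noise; treat as zero
  if (tot == 0 || hi <= tot * 1e-12)
    return(sentinel("frequency ratio (zero high-band power)"))
  sum(s$power[lowIdx]) / hi
}

#' @rdname fd-features
#' @export
featPKF <- function(s) {
  stopifnot(s$sided == "one")
  if (sum(s$power) == 0) return(sentinel("peak frequency (zero power)"))
  # near-ties (within 1e-9 relative) resolve to the lowest frequency
  s$freqs[which(s$power >= max(s$power) * (1 - 1e-9))[1L]]
}

#' Frequency energy in 10 Hz bins
#'
#' Squared two-sided FFT amplitude summed into contiguous 10 Hz bins across
#' the whole 0..fs index range (200 bins per channel at 2000 Hz).  Bin
#' totals conserve `sum(|X_j|^2)` exactly.
#'
#' @param s a two-sided [windowSpectrum()].
#' @param binHz bin width in Hz (default 10).
#' @return Numeric vector of `ceiling(fs / binHz)` energies.
#' @export
featFE <- function(s, binHz = 10) {
  stopifnot(s$sided == "two")
  nb <- as.integer(ceiling(s$fs / binHz))
  idx <- pmin(floor(s$freqs / binHz) + 1L, nb)
  as.vector(tapply(s$power, factor(idx, levels = seq_len(nb)), sum,
                   default = 0))
}
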