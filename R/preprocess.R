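# Pre-processing: band-pass + notch filtering, contraction trimming, and
# overlapped windowing.  Defaults reproduce standard surface-EMG practice:
# 10-500 Hz Butterworth band-pass, 50 Hz notch, 30% trimming (15% off each
# end of every contraction), 200 ms windows with a 100 ms hop.

#' Filter configuration
#'
#' @param bandLow,bandHigh band-pass edges in Hz (default 10 and 500).
#' @param notchFreq power-line notch centre in Hz (default 50).
#' @param butterOrder Butterworth band-pass order (default 4); applied
#'   forward-backward when `zeroPhase` so the effective magnitude response is
#'   of twice that order.
#' @param notchQ quality factor of the second-order IIR notch (default 30).
#' @param zeroPhase apply filters forward-backward (no phase distortion).
#' @return A `filterConfig` list.
#' @export
filterConfig <- function(bandLow = 10, bandHigh = 500, notchFreq = 50,
                         butterOrder = 4L, notchQ = 30, zeroPhase = TRUE) {
  stopifnot(bandLow > 0, bandLow < bandHigh, notchQ > 0, butterOrder >= 1)
  structure(list(bandLow = bandLow, bandHigh = bandHigh,
                 notchFreq = notchFreq, butterOrder = as.integer(butterOrder),
                 notchQ = notchQ, zeroPhase = zeroPhase),
            class = "filterConfig")
}

# biquad notch at f0 with quality Q (standard RBJ cookbook design)
notchCoefficients <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

applyFilter <- function(x, flt, zeroPhase) {
  if (zeroPhase) signal::filtfilt(flt, x) else signal::filter(flt, x)
}

#' Band-pass and notch filter a recording
#'
#' Applies a Butterworth band-pass followed by an IIR notch to every channel,
#' forward-backward (zero-phase) by default.
#'
#' @param rec an [EMGRecording-class].
#' @param cfg a [filterConfig()].
#' @return A filtered [EMGRecording-class] with the same shape and schedule.
#' @export
filterRecording <- function(rec, cfg = filterConfig()) {
  fs <- samplingRate(rec)
  if (cfg$bandHigh >= fs / 2)
    stop("band edges must lie below the Nyquist frequency (fs/2 = ",
         fs / 2, " Hz)")
  if (cfg$notchFreq < cfg$bandLow || cfg$notchFreq > cfg$bandHigh)
    stop("notch frequency must lie inside the pass band")
  # signal::butter() interprets the order per edge; n = order/2 gives a
  # band-pass whose polynomial order equals cfg$butterOrder
  bp <- signal::butter(max(1L, cfg$butterOrder %/% 2L),
                       c(cfg$bandLow, cfg$bandHigh) / (fs / 2), type = "pass")
  nc <- notchCoefficients(cfg$notchFreq, fs, cfg$notchQ)
  notch <- signal::Arma(b = nc$b, a = nc$a)
  out <- samples(rec)
  for (ch in seq_len(nrow(out))) {
    y <- applyFilter(out[ch, ], bp, cfg$zeroPhase)
    out[ch, ] <- applyFilter(y, notch, cfg$zeroPhase)
  }
  EMGRecording(out, fs = fs, schedule = schedule(rec),
               subjectId = subjectId(rec))
}

#' Trim contraction transition periods
#'
#' Shrinks every schedule entry symmetrically: an interval of length `L`
#' loses `round(L * fraction / 2)` samples from each end, discarding the
#' transition periods at contraction onset and offset.  Samples are left
#' untouched; only the schedule changes.  Rest entries are trimmed the same
#' way as contractions.
#'
#' @param rec an [EMGRecording-class].
#' @param fraction total fraction of each entry to discard (default 0.30,
#'   i.e. 15% from each end).
#' @return The recording with a shrunk schedule.
#' @export
trimContractions <- function(rec, fraction = 0.30) {
  stopifnot(fraction >= 0, fraction < 1)
  sched <- schedule(rec)
  if (nrow(sched) == 0L || fraction == 0) return(rec)
  len <- sched$end - sched$start
  cut <- round(len * fraction / 2)
  start <- sched$start + cut
  end <- sched$end - cut
  if (any(end - start < 2L))
    stop("schedule entry shorter than 2 samples after trimming")
  sched$start <- as.integer(start)
  sched$end <- as.integer(end)
  EMGRecording(samples(rec), fs = samplingRate(rec), schedule = sched,
               subjectId = subjectId(rec))
}

#' Cut overlapped analysis windows
#'
#' Within each schedule entry independently, windows of `winMs` milliseconds
#' are taken at hops of `stepMs` milliseconds while they fit entirely inside
#' the entry, so no window straddles a class boundary.  An entry shorter than
#' one window is skipped with a warning.
#'
#' @param rec an [EMGRecording-class] (typically filtered and trimmed).
#' @param winMs window length in ms (default 200).
#' @param stepMs hop in ms (default 100, i.e. 50% overlap).
#' @return An [EMGWindowSet-class]; an entry of length `L` contributes
#'   `floor((L - N) / step) + 1` windows.
#' @export
segmentWindows <- function(rec, winMs = 200, stepMs = 100) {
  fs <- samplingRate(rec)
  N <- as.integer(round(fs * winMs / 1000))
  step <- as.integer(round(fs * stepMs / 1000))
  stopifnot(N >= 1L, step >= 1L)
  sched <- schedule(rec)
  if (nrow(sched) == 0L) stop("recording has no movement schedule to segment")
  x <- samples(rec)
  offsets <- list(); labels <- character(); entries <- integer()
  for (i in seq_len(nrow(sched))) {
    L <- sched$end[i] - sched$start[i]
    if (L < N) {
      warning("schedule entry ", i, " (", sched$class[i], ", ", L,
              " samples) is shorter than one window; skipped")
      next
    }
    k <- (L - N) %/% step
    off <- sched$start[i] + step * (0:k)
    offsets[[length(offsets) + 1L]] <- off
    labels <- c(labels, rep(sched$class[i], k + 1L))
    entries <- c(entries, rep(i, k + 1L))
  }
  off <- as.integer(unlist(offsets))
  w <- length(off)
  arr <- array(0, dim = c(nrow(x), N, w))
  for (j in seq_len(w))
    arr[, , j] <- x[, (off[j] + 1L):(off[j] + N), drop = FALSE]
  new("EMGWindowSet", windows = arr, labels = labels,
      entry = as.integer(entries), step = step, fs = fs)
}
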