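# Shared fixtures, built in code.

# the hand-evaluated four-sample window used across the feature tests
x4 <- c(1, -2, 3, -4)

# a tiny labelled recording: deterministic samples, two channels
makeToyRecording <- function(nSamples = 2000, fs = 2000, nChannels = 2,
                             sched = data.frame(
                               class = c("open hand", "rest"),
                               start = c(0L, 1000L), end = c(1000L, 2000L))) {
  set.seed(123)
  EMGRecording(matrix(rnorm(nChannels * nSamples), nrow = nChannels),
               fs = fs, schedule = sched, subjectId = "toy")
}

# build a window set directly from a list of channels x N matrices
makeWindowSet <- function(wins, labels, fs = 2000,
                          entry = seq_along(labels), step = 200L) {
  arr <- array(0, dim = c(nrow(wins[[1]]), ncol(wins[[1]]), length(wins)))
  for (i in seq_along(wins)) arr[, , i] <- wins[[i]]
  new("EMGWindowSet", windows = arr, labels = labels,
      entry = as.integer(entry), step = as.integer(step), fs = fs)
}

# cache expensive shared objects across test files
.fixtureCache <- new.env(parent = emptyenv())

cachedEasyFeatures <- function(blocks = "FS", seed = 1L) {
  key <- paste0("fm_", blocks, "_", seed)
  if (is.null(.fixtureCache[[key]])) {
    rec <- generateSession(easyPreset(seed = seed))
    ws <- segmentWindows(trimContractions(filterRecording(rec)))
    .fixtureCache[[key]] <- assembleFeatures(ws, blocks)
  }
  .fixtureCache[[key]]
}

# one-window 4-channel window set with reproducible noise-like content
cachedSingleWindow <- function() {
  if (is.null(.fixtureCache$win1)) {
    set.seed(7)
    .fixtureCache$win1 <- makeWindowSet(
      list(matrix(rnorm(4 * 400), nrow = 4)), labels = "open hand",
      entry = 1L)
  }
  .fixtureCache$win1
}
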