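test_that("band-pass removes DC, notch kills 50 Hz, pass band is preserved", {
  fs <- 2000
  t <- seq(0, 4, by = 1 / fs)[-1]
  n <- length(t)
  sched <- data.frame(class = "open hand", start = 0L, end = as.integer(n))
  set.seed(5)
  noise <- rnorm(n, sd = 0.1)
  # DC offset is far below the 10 Hz band edge
  rec <- EMGRecording(matrix(1 + noise, 1), fs, sched)
  out <- samples(filterRecording(rec))[1, ]
  expect_lt(abs(mean(out[500:(n - 500)])), 0.01 * sqrt(mean(noise^2)))

  toneAmp <- function(freq, x) {
    seg <- x[1001:(1000 + 2000)]           # interior, clear of edge effects
    2 * Mod(fft(seg)[freq + 1]) / length(seg)
  }
  rec50 <- EMGRecording(matrix(sin(2 * pi * 50 * t), 1), fs, sched)
  amp50 <- toneAmp(50, samples(filterRecording(rec50))[1, ])
  expect_lt(20 * log10(amp50 / 1), -20)    # >= 20 dB attenuation

  rec200 <- EMGRecording(matrix(sin(2 * pi * 200 * t), 1), fs, sched)
  amp200 <- toneAmp(200, samples(filterRecording(rec200))[1, ])
  expect_lt(abs(amp200 - 1), 0.05)
})

test_that("filter configuration rejects edges at or above Nyquist", {
  rec <- makeToyRecording(fs = 800)
  expect_error(filterRecording(rec, filterConfig(bandHigh = 500)), "Nyquist")
})

test_that("filtering is linear", {
  rec <- makeToyRecording(nSamples = 4000)
  a <- samples(filterRecording(rec))
  rec2 <- EMGRecording(3.5 * samples(rec), samplingRate(rec), schedule(rec))
  b <- samples(filterRecording(rec2))
  expect_equal(b, 3.5 * a, tolerance = 1e-9)
})

test_that("contraction trimming removes 15% from each end", {
  rec <- makeToyRecording(sched = data.frame(class = "open hand",
                                             start = 0L, end = 1000L))
  tr <- schedule(trimContractions(rec, 0.30))
  expect_equal(c(tr$start, tr$end), c(150L, 850L))
  expect_equal(tr$end - tr$start, 700L)
  # identity at fraction zero
  expect_equal(schedule(trimContractions(rec, 0)), schedule(rec))
  # rounding rule on a 10-sample entry at fraction 0.9
  rec10 <- makeToyRecording(sched = data.frame(class = "open hand",
                                               start = 0L, end = 10L))
  tr10 <- schedule(trimContractions(rec10, 0.9))
  expect_equal(c(tr10$start, tr10$end), c(4L, 6L))
  # entries collapsing below 2 samples are rejected
  rec3 <- makeToyRecording(sched = data.frame(class = "open hand",
                                              start = 0L, end = 3L))
  expect_error(trimContractions(rec3, 0.9), "shorter than 2 samples")
})

test_that("windowing count follows floor((L - N)/step) + 1 per entry", {
  rec <- makeToyRecording(nSamples = 4000,
                          sched = data.frame(class = "open hand",
                                             start = 0L, end = 4000L))
  ws <- segmentWindows(rec)
  expect_equal(nWindows(ws), 19L)
  expect_equal(windowLength(ws), 400L)
  # exactly one window fits an entry of exactly N samples
  rec400 <- makeToyRecording(nSamples = 400,
                             sched = data.frame(class = "open hand",
                                                start = 0L, end = 400L))
  expect_equal(nWindows(segmentWindows(rec400)), 1L)
  # a 399-sample entry yields no window, with a warning
  rec399 <- makeToyRecording(nSamples = 399,
                             sched = data.frame(class = "open hand",
                                                start = 0L, end = 399L))
  expect_warning(ws399 <- segmentWindows(rec399), "shorter than one window")
  expect_equal(nWindows(ws399), 0L)
})

test_that("windows never straddle entries and counts hold on random schedules", {
  set.seed(42)
  for (i in 1:15) {
    fs <- 1000
    L1 <- sample(300:1200, 1); L2 <- sample(300:1200, 1)
    gap <- sample(0:50, 1)
    sched <- data.frame(class = c("open hand", "rest"),
                        start = c(0L, L1 + gap),
                        end = c(L1, L1 + gap + L2))
    rec <- EMGRecording(matrix(seq_len(L1 + gap + L2), 1), fs, sched)
    winMs <- sample(c(100, 200), 1); stepMs <- sample(c(50, 100), 1)
    N <- round(fs * winMs / 1000); step <- round(fs * stepMs / 1000)
    expected <- sum(pmax(0, (c(L1, L2) - N) %/% step + 1) * (c(L1, L2) >= N))
    ws <- suppressWarnings(segmentWindows(rec, winMs, stepMs))
    expect_equal(nWindows(ws), expected)
    # sample values index the original signal, so window content reveals
    # its position: every window must lie inside its entry
    if (nWindows(ws) > 0) {
      for (j in seq_len(nWindows(ws))) {
        vals <- windowData(ws, j)
        first <- vals[1]; last <- vals[length(vals)]
        ent <- sched[ws@entry[j], ]
        expect_gte(first, ent$start + 1)
        expect_lte(last, ent$end)
      }
    }
  }
})
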