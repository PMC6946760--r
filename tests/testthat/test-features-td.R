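# Closed-form fixture values for the x4 = c(1, -2, 3, -4) window were
# hand-evaluated from the printed feature definitions (sums of absolute
# values/differences, central moments, variance ratios).

test_that("amplitude and difference features reproduce hand-computed values", {
  expect_equal(featMAV(x4), 2.5)
  expect_equal(featIAV(x4), 10)
  expect_equal(featSTD(x4), sqrt(29 / 3), tolerance = 1e-12)
  expect_equal(featVAR(x4), 10)                  # uncentred: 30 / 3
  expect_equal(featWL(x4), 15)                   # 3 + 5 + 7
  expect_equal(featDAMV(x4), 3.75)               # 15 / 4
  expect_equal(featDASDV(x4), sqrt(83 / 3), tolerance = 1e-12)
  expect_equal(featMFL(x4), log10(sqrt(83)), tolerance = 1e-12)
  expect_equal(featPerc75(x4), 3)                # 3 of 4 sorted values below 3
  # trivial anchors
  expect_equal(featMAV(rep(0, 4)), 0)
  expect_equal(featMAV(rep(3, 4)), 3)
  expect_equal(featSTD(rep(2, 4)), 0)
  expect_equal(featWL(c(0, 1, 2, 3)), 3)
  expect_equal(featDASDV(rep(1, 4)), 0)
  expect_equal(featPerc75(rep(7, 4)), 7)
  expect_equal(featPerc75(1:100), 76)            # 75 values lie below 76
})

test_that("counting features follow their strict sign/threshold rules", {
  expect_equal(featZC(x4), 3)
  expect_equal(featZC(rep(1, 4)), 0)
  expect_equal(featZC(c(1, 0, -1)), 0)           # zeros break strict changes
  expect_equal(featSSC(x4), 2)                   # products 15 and 35 > 0
  expect_equal(featSSC(x4, thresholdConfig(sscThreshold = 20)), 1)
  expect_equal(featSSC(1:5), 0)
  expect_equal(featWAM(x4, thresholdConfig(wamThreshold = 4)), 2)
  expect_equal(featWAM(rep(2, 4)), 0)
  set.seed(1); z <- rnorm(50)
  expect_equal(featWAM(z, thresholdConfig(wamThreshold = 0)),
               sum(diff(z) != 0))
})

test_that("peaks above window RMS give NP, MPV and MFV", {
  expect_equal(featPeaks(x4), c(NP = 1, MPV = 3, MFV = 0))  # RMS ~ 2.74
  expect_equal(featPeaks(rep(0, 4)), c(NP = 0, MPV = 0, MFV = 0))
  expect_equal(featPeaks(c(5, 5, 1, 1)), c(NP = 2, MPV = 5, MFV = 0))
  expect_equal(featPeaks(c(6, 10, 1, 1))[["MFV"]], 4)  # RMS ~ 5.87, peaks 6, 10
})

test_that("moment features match central-moment arithmetic", {
  expect_equal(featSkew(x4), 0)                  # symmetric values
  expect_equal(featKurt(x4), 77.5625 / 7.25^2, tolerance = 1e-12)
  expect_warning(expect_true(is.nan(featSkew(rep(1, 4)))))
  expect_warning(expect_true(is.nan(featKurt(rep(1, 4)))))
  set.seed(2)
  g <- rnorm(1e5)
  expect_equal(featKurt(g), 3, tolerance = 0.1 / 3)
  expect_equal(featSkew(g), 0, tolerance = 0.05)
})

test_that("Hjorth parameters use mean-subtracted variances", {
  expect_equal(featHjorthMobility(x4), sqrt((112 / 3) / (29 / 3)),
               tolerance = 1e-12)
  expect_warning(expect_true(is.nan(featHjorthMobility(rep(2, 4)))))
  # a densely sampled pure sine has complexity ~ 1
  t <- seq_len(400) / 2000
  sine <- sin(2 * pi * 5 * t)
  expect_equal(featHjorthComplexity(sine), 1, tolerance = 0.05)
  # both are amplitude invariant
  set.seed(3); z <- rnorm(400)
  expect_equal(featHjorthMobility(7 * z), featHjorthMobility(z),
               tolerance = 1e-12)
  expect_equal(featHjorthComplexity(7 * z), featHjorthComplexity(z),
               tolerance = 1e-12)
})

test_that("curve length and Higuchi dimension follow the printed form", {
  expect_equal(featFDim(x4, 1), 15 * 3 / 4)
  expect_equal(featFDim(rep(5, 4), 2), 0)
  expect_error(featFDim(x4, 4), "k must satisfy")
  # independent brute-force evaluation of the printed sum
  bruteFDim <- function(x, k) {
    n <- length(x); tot <- 0
    for (i in seq_len((n - 1) %/% k))
      tot <- tot + abs(x[i * k + 1] - x[(i - 1) * k + 1])
    tot * (n - 1) / n / k
  }
  set.seed(4); z <- rnorm(400)
  for (k in c(1, 3, 5, 10))
    expect_equal(featFDim(z, k), bruteFDim(z, k), tolerance = 1e-12)
  # a straight line has fractal dimension ~ 1; white noise lands in (1, 2.2)
  ramp <- 0:399
  expect_equal(featHFD(ramp), 1.01, tolerance = 0.02)
  hfdNoise <- featHFD(z)
  expect_gt(hfdNoise, 1); expect_lt(hfdNoise, 2.2)
  expect_warning(expect_true(is.nan(featHFD(rep(1, 400)))))
})

test_that("channel correlation is the absolute Pearson coefficient", {
  set.seed(5); a <- rnorm(50); b <- rnorm(50)
  expect_equal(featCor(a, a), 1)
  expect_equal(featCor(a, -a), 1)
  expect_equal(featCor(a, b), abs(stats::cor(a, b)), tolerance = 1e-12)
  expect_equal(featCor(x4, c(1, -2, 3, 4)),
               abs(stats::cor(x4, c(1, -2, 3, 4))), tolerance = 1e-12)
  expect_warning(r0 <- featCor(rep(1, 4), x4), "constant")
  expect_equal(r0, 0)
})

test_that("multi-channel energy ratios enumerate (j, k) pairs correctly", {
  same <- matrix(rep(x4, each = 4), nrow = 4, byrow = TRUE)
  same <- rbind(x4, x4, x4, x4)
  expect_equal(unname(featEnergyRatio(same)), c(1, 1, 1))
  win <- rbind(c(1, 0), c(sqrt(2), 0), c(2, 0), c(2 * sqrt(2), 0))
  er <- featEnergyRatio(win)   # energies 1, 2, 4, 8
  expect_equal(names(er), c("ch2_ch3", "ch2_ch4", "ch3_ch4"))
  expect_equal(unname(er), c(2 / 16, 2 / 64, 4 / 64))
})

test_that("MAV slope assigns forward differences with trailing zero", {
  expect_equal(featMAVS(c(2, 5, 5)), c(3, 0, 0))
  expect_equal(featMAVS(4), 0)
  expect_equal(featMAVS(rep(1.5, 5)), rep(0, 5))
})

test_that("histogram counts span the window range and conserve N", {
  expect_equal(featHist(x4), c(1, 0, 1, 0, 0, 0, 1, 0, 1))
  expect_equal(featHist(rep(2, 4)), c(4, rep(0, 8)))
  set.seed(6)
  for (i in 1:10) {
    z <- rnorm(sample(10:400, 1))
    expect_equal(sum(featHist(z)), length(z))
  }
})

test_that("algebraic identities link the difference-based features", {
  set.seed(7)
  for (i in 1:10) {
    z <- rnorm(400)
    expect_equal(featDAMV(z), featWL(z) / length(z), tolerance = 1e-12)
    expect_equal(featIAV(z), length(z) * featMAV(z), tolerance = 1e-12)
    expect_equal(featDASDV(z)^2 * (length(z) - 1), 10^(2 * featMFL(z)),
                 tolerance = 1e-9)
  }
})

test_that("features scale as expected under amplitude changes", {
  set.seed(8); z <- rnorm(400); c <- 4.2
  linear <- list(featMAV, featSTD, featWL, featDAMV, featDASDV, featIAV)
  for (f in linear) expect_equal(f(c * z), c * f(z), tolerance = 1e-9)
  invariant <- list(featZC, function(x) featSSC(x), featHjorthMobility,
                    featHjorthComplexity, featSkew, featKurt)
  for (f in invariant) expect_equal(f(c * z), f(z), tolerance = 1e-9)
})
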