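# Wavelet fixture: the transform of sin(1:32) was computed with an
# independent reference implementation of the periodized DWT/WPT and the
# resulting coefficients frozen here.

test_that("periodized coif4 DWT matches the independent reference", {
  x <- sin(1:32)
  dec <- dwtDecompose(x, "coif4", levels = 1L)
  refA <- c(-1.35310000585029, 0.632148968910977, 1.21185812862544,
            -1.03619910519505, -0.408308440498102, 1.3952391216793,
            -0.7573646493483, -0.76439727010754, 1.39356766098935,
            -0.395460277162696, -1.0644282915312, 1.28137024139933,
            -0.0019712970380976, -1.2802335186996, 1.07005364351841,
            0.379470383072327)
  refD <- c(0.140436412579393, -0.102498525808637, -0.0361993795815459,
            0.128254149451686, -0.0696786339514906, -0.0704203315508996,
            0.12830699853627, -0.0363697558361714, -0.0980366808618404,
            0.117965065048645, -3.51742854261813e-06, -0.120135955683236,
            0.112644044701364, -0.016211594250254, 0.162411226827668,
            -0.0775240261395206)
  expect_equal(dec$a, refA, tolerance = 1e-12)
  expect_equal(dec$d, refD, tolerance = 1e-12)
  lvl4 <- dwtDecompose(x, "coif4", levels = 4L)
  expect_equal(lvl4$a, c(-0.00272152930099216, 0.109581377348651),
               tolerance = 1e-12)
  expect_equal(lvl4$d, c(0.094845489654962, 0.00520531318693061),
               tolerance = 1e-12)
})

test_that("periodized sym5 packet tree matches reference energies in frequency order", {
  x <- sin(1:32)
  wpt <- wptDecompose(x, "sym5", levels = 4L)
  refE <- c(0.00575837843166148, 0.0309002435853858, 0.710672009473774,
            0.627544218755537, 4.0730580389022, 9.78399265082784,
            0.169686231895855, 0.0469686598873241, 0.00528621347818307,
            0.0201930364953945, 0.305747315408719, 0.180841031044884,
            0.0187270040896644, 0.0184446414479967, 0.00395024480149695,
            0.00258029244971765)
  expect_equal(unname(wpt$energies), refE, tolerance = 1e-12)
  expect_equal(wpt$subspaces$s01,
               c(0.0484870063979287, 0.0583728416494238), tolerance = 1e-12)
})

test_that("400-sample windows give 25-coefficient level-4 subbands", {
  set.seed(13); z <- rnorm(400)
  dec <- dwtDecompose(z)
  expect_equal(length(dec$a), 25L)
  expect_equal(length(dec$d), 25L)
  wpt <- wptDecompose(z)
  expect_equal(length(wpt$subspaces), 16L)
  expect_true(all(vapply(wpt$subspaces, length, 1L) == 25L))
  expect_equal(wpt$nPerSubspace, 25)
  expect_error(dwtDecompose(rnorm(8)), "shorter")
  expect_error(wptDecompose(rnorm(8)), "shorter")
})

test_that("both transforms conserve energy under periodization", {
  set.seed(14)
  for (i in 1:5) {
    z <- rnorm(400)
    dec <- dwtDecompose(z)
    eDWT <- sum(dec$a^2) + sum(unlist(dec$details)^2)
    expect_equal(eDWT, sum(z^2), tolerance = 1e-9)
    wpt <- wptDecompose(z)
    expect_equal(wpt$totalEnergy, sum(z^2), tolerance = 1e-9)
  }
  zero <- dwtDecompose(rep(0, 64))
  expect_true(all(zero$combined == 0))
  expect_equal(wptDecompose(rep(0, 64))$totalEnergy, 0)
})

test_that("DWT statistics reuse the time-domain operators on coefficients", {
  fake <- list(combined = x4)
  st <- featDWTStats(fake)
  expect_equal(st[["STD"]], sqrt(29 / 3), tolerance = 1e-12)
  expect_equal(st[["VAR"]], 10)
  expect_equal(st[["WL"]], 15)
  expect_equal(st[["ENERGY"]], 30)
  expect_equal(st[["MAXAV"]], 4)
  expect_equal(st[["ZC"]], 3)
  expect_equal(st[["MEAN"]], -0.5)
  expect_equal(st[["MAV"]], 2.5)
})

test_that("packet subspace features follow their logarithmic definitions", {
  fake <- list(subspaces = list(s01 = rep(2, 25), s02 = rep(exp(1), 25)),
               energies = c(s01 = 4 * 25, s02 = exp(2) * 25),
               totalEnergy = 4 * 25 + exp(2) * 25, nPerSubspace = 25)
  expect_equal(unname(featLogRMS(fake)), c(log(2), 1), tolerance = 1e-12)
  expect_equal(unname(featNLE(fake)), c(log(4), 2), tolerance = 1e-12)
  zeroed <- list(subspaces = list(s01 = rep(0, 25)),
                 energies = c(s01 = 0), totalEnergy = 0, nPerSubspace = 25)
  expect_warning(expect_true(is.nan(featLogRMS(zeroed)[[1]])))
  expect_warning(expect_true(all(is.nan(featRelativeEnergy(zeroed)))))
})

test_that("relative energies normalise to one and match a brute-force sum", {
  set.seed(15); z <- rnorm(400)
  wpt <- wptDecompose(z)
  re <- featRelativeEnergy(wpt)
  expect_equal(sum(re), 1, tolerance = 1e-12)
  brute <- vapply(wpt$subspaces, function(w) sum(w^2), numeric(1)) /
    sum(vapply(wpt$subspaces, function(w) sum(w^2), numeric(1)))
  expect_equal(re, brute, tolerance = 1e-12)
  # NLE = 2 * LogRMS holds identically
  expect_equal(featNLE(wpt), 2 * featLogRMS(wpt), tolerance = 1e-12)
})
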