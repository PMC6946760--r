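# Periodized discrete wavelet transform and full wavelet-packet tree.
# Implemented in-package (no wavelet package ships with this R stack).
#
# Analysis step with periodization: for an even-length signal x (0-based) and
# a filter f of even length L,
#   y[k] = sum_{m=0}^{L-1} f[m] * x[(2k + L/2 - m) mod n],  k = 0..n/2-1.
# This keeps exactly n/2 coefficients per branch, makes the transform
# orthonormal (energy is conserved to float precision) and gives every
# level-j packet subspace exactly N/2^j coefficients.

# Standard orthonormal filter banks (decomposition low-pass; the high-pass
# is the quadrature mirror).  coif4 = 4th-order Coiflet (24 taps),
# sym5 = 5th-order Symmlet (10 taps).
waveletFilters <- function(wavelet = c("coif4", "sym5")) {
  wavelet <- match.arg(wavelet)
  lo <- switch(wavelet,
    coif4 = c(-1.7849909144933469e-06, -3.259647940030751e-06,
               3.1229861599195265e-05,  6.233885431278719e-05,
              -0.0002599743371222568,  -0.0005890202246332165,
               0.0012665610789256603,   0.0037514346971460866,
              -0.0056582838001308835,  -0.015211728187697211,
               0.02508225333794961,     0.03933442260558915,
              -0.09622042453595264,    -0.06662747236681717,
               0.43438603311435653,     0.7822389344242826,
               0.41530842700068227,    -0.05607731960356926,
              -0.08126671024919373,     0.02668230466960483,
               0.01606894713157503,    -0.007346167936268051,
              -0.001629492425226786,    0.000892313902537003),
    sym5  = c( 0.027333068345077982,    0.029519490925774643,
              -0.039134249302383094,    0.1993975339773936,
               0.7234076904024206,      0.6339789634582119,
               0.01660210576452232,    -0.17532808990845047,
              -0.021101834024758855,    0.019538882735286728))
  L <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(L)   # QMF: hi[m] = (-1)^(m+1) lo[L-1-m], 0-based m
  list(lo = lo, hi = hi, length = L)
}

# one periodized analysis step; x must have even length
dwtStep <- function(x, flt) {
  n <- length(x)
  if (n %% 2L != 0L) stop("periodized DWT step needs an even-length input")
  L <- flt$length
  k <- 0:(n %/% 2L - 1L)
  idx <- outer(2L * k + L %/% 2L, 0:(L - 1L), `-`) %% n + 1L
  X <- matrix(x[idx], nrow = length(k))
  list(a = as.vector(X %*% flt$lo), d = as.vector(X %*% flt$hi))
}

#' Multi-level discrete wavelet transform
#'
#' Periodized DWT of one window channel; default 4 levels with the 4th-order
#' Coiflet, so a 400-sample window yields 25 approximation and 25 detail
#' coefficients at the final level.
#'
#' @param x numeric vector (length divisible by `2^levels`).
#' @param wavelet `"coif4"` (default) or `"sym5"`.
#' @param levels decomposition depth (default 4).
#' @return List with `a` (final approximation), `d` (final detail),
#'   `details` (detail coefficients per level) and `combined` (`c(a, d)`).
#' @export
dwtDecompose <- function(x, wavelet = "coif4", levels = 4L) {
  if (length(x) < 2^levels) stop("window shorter than 2^levels samples")
  flt <- waveletFilters(wavelet)
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    st <- dwtStep(a, flt)
    a <- st$a
    details[[lev]] <- st$d
  }
  list(a = a, d = details[[levels]], details = details, combined = c(a, details[[levels]]))
}

grayCode <- function(g) bitwXor(g, bitwShiftR(g, 1L))

#' Full wavelet-packet decomposition
#'
#' Periodized wavelet-packet tree; default level 4 with the 5th-order
#' Symmlet, giving 16 leaf subspaces of `N / 16` coefficients each, returned
#' in frequency order (lowest band first).
#'
#' @param x numeric vector (length divisible by `2^levels`).
#' @param wavelet `"sym5"` (default) or `"coif4"`.
#' @param levels decomposition depth (default 4).
#' @return List with `subspaces` (list of coefficient vectors, frequency
#'   order), `energies`, `totalEnergy` and `nPerSubspace`.
#' @export
wptDecompose <- function(x, wavelet = "sym5", levels = 4L) {
  if (length(x) < 2^levels) stop("window shorter than 2^levels samples")
  flt <- waveletFilters(wavelet)
  nodes <- list(x)                        # Paley (natural) order at each level
  for (lev in seq_len(levels)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      st <- dwtStep(nodes[[i]], flt)
      nxt[[2L * i - 1L]] <- st$a
      nxt[[2L * i]] <- st$d
    }
    nodes <- nxt
  }
  freqOrder <- grayCode(0:(2^levels - 1L)) + 1L
  sub <- nodes[freqOrder]
  names(sub) <- sprintf("s%02d", seq_along(sub))
  energies <- vapply(sub, function(w) sum(w^2), numeric(1))
  list(subspaces = sub, energies = energies, totalEnergy = sum(energies),
       nPerSubspace = length(x) / 2^levels)
}
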