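# Feature-block registry and window-set assembly.  Column order is a pure
# function of the requested block list and the channel count: blocks appear
# in the requested order; within a block, channels in order; within a
# channel, bins/subspaces in order.  Column identifiers follow the
# `block.feature.index` scheme used by the feature CSV writer.

# canonical block lists, in the conventional numbering per domain
TD_BLOCKS <- c("MAV", "STD", "VAR", "WL", "ZC", "NP", "MPV", "MFV", "SSC",
               "COR", "DAMV", "FDIM", "MFL", "HFD", "SKEW", "IAV", "HMOB",
               "HCOM", "ER", "DASDV", "WAM", "MAVS", "KURT", "PERC", "HIST")
FD_BLOCKS <- c("WL_FD", "MNF", "MDF", "MPK", "STDPK", "FR", "PKF", "FE")
TFD_BLOCKS <- c("STD_DWT", "VAR_DWT", "WL_DWT", "ENERGY_DWT", "MAXAV_DWT",
                "ZC_DWT", "MEAN_DWT", "MAV_DWT", "LOGRMS", "RE", "NLE")

# per-channel scalar TD features (block name -> function(x, cfg))
TD_SCALARS <- list(
  MAV = function(x, cfg) featMAV(x),
  STD = function(x, cfg) featSTD(x),
  VAR = function(x, cfg) featVAR(x),
  WL = function(x, cfg) featWL(x),
  ZC = function(x, cfg) featZC(x),
  NP = function(x, cfg) featPeaks(x)[["NP"]],
  MPV = function(x, cfg) featPeaks(x)[["MPV"]],
  MFV = function(x, cfg) featPeaks(x)[["MFV"]],
  SSC = function(x, cfg) featSSC(x, cfg),
  DAMV = function(x, cfg) featDAMV(x),
  FDIM = function(x, cfg) featFDim(x, cfg$fdimK),
  MFL = function(x, cfg) featMFL(x),
  HFD = function(x, cfg) featHFD(x, cfg),
  SKEW = function(x, cfg) featSkew(x),
  IAV = function(x, cfg) featIAV(x),
  HMOB = function(x, cfg) featHjorthMobility(x),
  HCOM = function(x, cfg) featHjorthComplexity(x),
  DASDV = function(x, cfg) featDASDV(x),
  WAM = function(x, cfg) featWAM(x, cfg),
  KURT = function(x, cfg) featKurt(x),
  PERC = function(x, cfg) featPerc75(x))

# one-sided-spectrum scalar FD features (block name -> function(s, bands))
FD_SCALARS <- list(
  MNF = function(s, bands) featMNF(s),
  MDF = function(s, bands) featMDF(s),
  MPK = function(s, bands) featSpectralPeaks(s)[["MPK"]],
  STDPK = function(s, bands) featSpectralPeaks(s)[["STDPK"]],
  FR = function(s, bands) featFR(s, bands),
  PKF = function(s, bands) featPKF(s))

DWT_STATS <- c(STD_DWT = "STD", VAR_DWT = "VAR", WL_DWT = "WL",
               ENERGY_DWT = "ENERGY", MAXAV_DWT = "MAXAV", ZC_DWT = "ZC",
               MEAN_DWT = "MEAN", MAV_DWT = "MAV")
WPT_FEATS <- c(LOGRMS = "LOGRMS", RE = "RE", NLE = "NLE")

#' Feature blocks and named feature sets
#'
#' `featureBlocks()` lists the implemented feature block names per domain.
#' `featureSet()` resolves a named set: `"TD_ALL"`, `"FD_ALL"`, `"TFD_ALL"`,
#' `"ALL"`, the proposed compact set `"FS"` (waveform length, uncentred
#' variance, channel correlation, Hjorth mobility and complexity) or the
#' classic Hudgins set `"HUDGINS"` (MAV, WL, SSC, ZC, DAMV).
#'
#' @param name feature-set name (case-insensitive).
#' @return Character vector of block names.
#' @export
featureBlocks <- function() {
  list(td = TD_BLOCKS, fd = FD_BLOCKS, tfd = TFD_BLOCKS)
}

#' @rdname featureBlocks
#' @export
featureSet <- function(name) {
  switch(toupper(name),
    TD_ALL = TD_BLOCKS,
    FD_ALL = FD_BLOCKS,
    TFD_ALL = TFD_BLOCKS,
    ALL = c(TD_BLOCKS, FD_BLOCKS, TFD_BLOCKS),
    FS = c("WL", "VAR", "COR", "HMOB", "HCOM"),
    HUDGINS = c("MAV", "WL", "SSC", "ZC", "DAMV"),
    stop("unknown feature set: ", name))
}

channelPairs <- function(M) {
  out <- character(0)
  for (a in seq_len(M - 1L)) for (b in (a + 1L):M)
    out <- c(out, sprintf("ch%d_ch%d", a, b))
  out
}

erPairs <- function(M) {
  out <- character(0)
  for (j in 2:(M - 1L)) for (k in (j + 1L):M)
    out <- c(out, sprintf("ch%d_ch%d", j, k))
  out
}

# column annotation for one block given channel count and configs
blockInfo <- function(block, M, cfg, fs, levels = 4L) {
  ch <- sprintf("ch%d", seq_len(M))
  if (block %in% names(TD_SCALARS) || block %in% names(DWT_STATS) ||
      block %in% c("WL_FD", names(FD_SCALARS)))
    return(data.frame(block = block, feature = block, index = ch))
  switch(block,
    COR = data.frame(block = block, feature = block, index = channelPairs(M)),
    ER = data.frame(block = block, feature = block, index = erPairs(M)),
    MAVS = data.frame(block = block, feature = block, index = ch),
    HIST = data.frame(block = block,
                      feature = rep(ch, each = cfg$histBins),
                      index = rep(sprintf("bin%d", seq_len(cfg$histBins)), M)),
    FE = {
      nb <- as.integer(ceiling(fs / 10))
      data.frame(block = block, feature = rep(ch, each = nb),
                 index = rep(sprintf("bin%d", seq_len(nb)), M))
    },
    LOGRMS = , RE = , NLE = {
      ns <- 2L^levels
      data.frame(block = block, feature = rep(ch, each = ns),
                 index = rep(sprintf("s%02d", seq_len(ns)), M))
    },
    stop("unknown feature block: ", block))
}

#' Assemble a feature matrix from a window set
#'
#' Computes the requested feature blocks for every window and concatenates
#' them into an [EMGFeatureMatrix-class].  With 4 channels and 400-sample
#' windows the full domains yield 133 (TD), 828 (FD) and 224 (TFD) columns.
#'
#' @param ws an [EMGWindowSet-class].
#' @param blocks character vector of block names (see [featureBlocks()]), or
#'   a set name accepted by [featureSet()].
#' @param cfg a [thresholdConfig()].
#' @param bands a [bandConfig()] for the frequency ratio.
#' @param dwtWavelet,wptWavelet wavelet families for the time-frequency
#'   blocks (defaults `"coif4"` / `"sym5"`).
#' @param levels wavelet decomposition depth (default 4).
#' @return An [EMGFeatureMatrix-class] with deterministic column order.
#' @export
assembleFeatures <- function(ws, blocks = "TD_ALL", cfg = thresholdConfig(),
                             bands = bandConfig(), dwtWavelet = "coif4",
                             wptWavelet = "sym5", levels = 4L) {
  if (length(blocks) == 1L &&
      toupper(blocks) %in% c("TD_ALL", "FD_ALL", "TFD_ALL", "ALL", "FS", "HUDGINS"))
    blocks <- featureSet(blocks)
  known <- c(TD_BLOCKS, FD_BLOCKS, TFD_BLOCKS)
  if (!all(blocks %in% known))
    stop("unknown feature block(s): ",
         paste(setdiff(blocks, known), collapse = ", "))
  M <- nChannels(ws); w <- nWindows(ws); fs <- samplingRate(ws)
  infos <- lapply(blocks, blockInfo, M = M, cfg = cfg, fs = fs, levels = levels)
  names(infos) <- NULL
  arities <- vapply(infos, nrow, 1L)
  needSpec1 <- any(blocks %in% names(FD_SCALARS))
  needSpec2 <- any(blocks %in% c("WL_FD", "FE"))
  needDWT <- any(blocks %in% names(DWT_STATS))
  needWPT <- any(blocks %in% names(WPT_FEATS))
  vals <- lapply(arities, function(a) matrix(NA_real_, nrow = w, ncol = a))
  mavMat <- if ("MAVS" %in% blocks) matrix(0, nrow = w, ncol = M) else NULL
  for (j in seq_len(w)) {
    win <- ws@windows[, , j, drop = FALSE]
    dim(win) <- dim(win)[1:2]
    chans <- lapply(seq_len(M), function(ch) win[ch, ])
    s1 <- if (needSpec1) lapply(chans, windowSpectrum, fs = fs, sided = "one")
    s2 <- if (needSpec2) lapply(chans, windowSpectrum, fs = fs, sided = "two")
    dwt <- if (needDWT)
      lapply(chans, function(x) featDWTStats(dwtDecompose(x, dwtWavelet, levels)))
    wpt <- if (needWPT)
      lapply(chans, wptDecompose, wavelet = wptWavelet, levels = levels)
    if (!is.null(mavMat)) mavMat[j, ] <- vapply(chans, featMAV, numeric(1))
    for (b in seq_along(blocks)) {
      block <- blocks[b]
      vals[[b]][j, ] <-
        if (block %in% names(TD_SCALARS)) {
          f <- TD_SCALARS[[block]]
          vapply(chans, f, numeric(1), cfg = cfg)
        } else if (block == "COR") {
          out <- numeric(0)
          for (a in seq_len(M - 1L)) for (bb in (a + 1L):M)
            out <- c(out, featCor(chans[[a]], chans[[bb]]))
          out
        } else if (block == "ER") {
          featEnergyRatio(win)
        } else if (block == "HIST") {
          unlist(lapply(chans, featHist, cfg = cfg))
        } else if (block == "MAVS") {
          rep(0, M)  # filled after the window loop
        } else if (block == "WL_FD") {
          vapply(s2, featWLFD, numeric(1))
        } else if (block %in% names(FD_SCALARS)) {
          f <- FD_SCALARS[[block]]
          vapply(s1, f, numeric(1), bands = bands)
        } else if (block == "FE") {
          unlist(lapply(s2, featFE))
        } else if (block %in% names(DWT_STATS)) {
          vapply(dwt, `[[`, numeric(1), DWT_STATS[[block]])
        } else if (block == "LOGRMS") {
          unlist(lapply(wpt, featLogRMS))
        } else if (block == "RE") {
          unlist(lapply(wpt, featRelativeEnergy))
        } else if (block == "NLE") {
          unlist(lapply(wpt, featNLE))
        }
    }
  }
  if (!is.null(mavMat)) {
    b <- which(blocks == "MAVS")
    for (ent in unique(ws@entry)) {
      rows <- which(ws@entry == ent)
      for (ch in seq_len(M))
        vals[[b]][rows, ch] <- featMAVS(mavMat[rows, ch])
    }
  }
  EMGFeatureMatrix(do.call(cbind, vals), do.call(rbind, infos),
                   labels = windowLabels(ws), entry = ws@entry)
}
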