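# Readers and writers for the supported interchange formats.
#
# Recording CSV dialect: line 1 is the comment line `# fs=<Hz>`, line 2 a
# header `ch1,...,chM`, then one row per sample with one column per channel.
# The movement schedule travels in a sidecar CSV with header `class,start,end`
# (0-based, half-open sample intervals).

#' Read a multi-channel EMG recording
#'
#' @param path path to the recording (`.csv` dialect described below, or a
#'   multi-channel PCM16/float32 `.wav`).
#' @param format `"csv"` or `"wav"`; guessed from the file extension by
#'   default.
#' @param schedulePath optional sidecar schedule CSV (`class,start,end`,
#'   0-based half-open intervals); defaults to `<path>.schedule.csv` when that
#'   file exists.
#' @param subjectId subject identifier to attach.
#'
#' @details The CSV dialect stores the sampling rate on a first comment line
#' `# fs=2000`, followed by a `ch1..chM` header and one column per channel.
#' @return An [EMGRecording-class].
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, format = c("auto", "csv", "wav"),
                          schedulePath = NULL, subjectId = "subject") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "wav") {
    wav <- readWavFile(path)
    samplesMat <- wav$samples
    fs <- wav$fs
  } else {
    header <- readLines(path, n = 1L)
    m <- regmatches(header, regexec("^#\\s*fs=([0-9.]+)\\s*$", header))[[1L]]
    if (length(m) < 2L)
      stop("malformed recording CSV: first line must be `# fs=<Hz>`")
    fs <- as.numeric(m[2L])
    df <- read.csv(path, comment.char = "#", check.names = FALSE)
    samplesMat <- t(as.matrix(df))
  }
  if (is.null(schedulePath)) {
    cand <- paste0(path, ".schedule.csv")
    if (file.exists(cand)) schedulePath <- cand
  }
  sched <- if (is.null(schedulePath)) emptySchedule() else readSchedule(schedulePath)
  EMGRecording(samplesMat, fs = fs, schedule = sched, subjectId = subjectId)
}

#' @rdname readRecording
#' @param x an [EMGRecording-class] to write.
#' @export
writeRecording <- function(x, path, format = c("auto", "csv", "wav"),
                           schedulePath = paste0(path, ".schedule.csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv"
  if (format == "wav") {
    writeWavFile(samples(x), samplingRate(x), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fs=%s", format(samplingRate(x), scientific = FALSE)), con)
    df <- as.data.frame(t(samples(x)))
    names(df) <- paste0("ch", seq_len(nChannels(x)))
    write.csv(df, con, row.names = FALSE)
  }
  if (nrow(schedule(x)) > 0L && !is.null(schedulePath))
    writeSchedule(schedule(x), schedulePath)
  invisible(path)
}

#' @rdname readRecording
#' @export
readSchedule <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class", "start", "end") %in% names(df)))
    stop("schedule CSV needs columns class,start,end")
  df <- df[, c("class", "start", "end")]
  df$class <- as.character(df$class)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  msg <- validSchedule(df, Inf)
  if (!isTRUE(msg)) stop("invalid schedule: ", msg)
  df
}

#' @rdname readRecording
#' @param sched a schedule `data.frame` (`class`, `start`, `end`).
#' @export
writeSchedule <- function(sched, path) {
  write.csv(sched, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write feature matrices as CSV
#'
#' One header row of `block.feature.index` column names, one data row per
#' window, and a final `label` column.  `readFeatureMatrix(writeFeatureMatrix(x))`
#' reproduces `x` to better than 1e-12.
#'
#' @param fm an [EMGFeatureMatrix-class].
#' @param path output CSV path.
#' @return `writeFeatureMatrix` returns `path`; `readFeatureMatrix` an
#'   [EMGFeatureMatrix-class].
#' @export
writeFeatureMatrix <- function(fm, path) {
  vals <- featureValues(fm)
  txt <- matrix(sprintf("%.17g", vals), nrow = nrow(vals), ncol = ncol(vals))
  df <- as.data.frame(txt, stringsAsFactors = FALSE,
                      col.names = featureIds(featureInfo(fm)))
  names(df) <- featureIds(featureInfo(fm))
  df$label <- windowLabels(fm)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stop("feature CSV must end with a label column")
  labels <- as.character(df$label)
  df$label <- NULL
  parts <- strsplit(names(df), ".", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) stop("malformed feature column name(s): ",
                     paste(names(df)[bad], collapse = ", "))
  info <- data.frame(block = vapply(parts, `[`, "", 1L),
                     feature = vapply(parts, `[`, "", 2L),
                     index = vapply(parts, `[`, "", 3L))
  vals <- as.matrix(as.data.frame(lapply(df, as.numeric)))
  colnames(vals) <- NULL
  EMGFeatureMatrix(vals, info, labels)
}
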