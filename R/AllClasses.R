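# Core data containers.  Sample indexing convention throughout: schedule
# intervals are 0-based, half-open [start, end) in samples, so arithmetic for
# trimming and windowing needs no +/-1 bookkeeping.

#' Multi-channel surface EMG recording
#'
#' Holds a channels x samples matrix (millivolts), its sampling rate, an
#' opaque subject identifier and a movement schedule.  The schedule is a
#' `data.frame` with columns `class` (character), `start`, `end` (integer
#' sample indices, 0-based, half-open `[start, end)`), sorted and
#' non-overlapping.
#'
#' @slot samples numeric matrix, channels x n_samples.
#' @slot fs sampling rate in Hz.
#' @slot subjectId subject identifier.
#' @slot schedule movement schedule `data.frame` (`class`, `start`, `end`).
#'
#' @param x an `EMGRecording` (accessors).
#' @aliases samples samplingRate subjectId schedule nChannels
#' @export
setClass("EMGRecording",
  representation(samples = "matrix", fs = "numeric",
                 subjectId = "character", schedule = "data.frame"))

validSchedule <- function(schedule, nSamples) {
  if (!all(c("class", "start", "end") %in% names(schedule)))
    return("schedule must have columns class, start, end")
  if (nrow(schedule) == 0L) return(TRUE)
  if (!is.character(schedule$class)) return("schedule$class must be character")
  s <- schedule$start; e <- schedule$end
  if (any(s < 0) || any(e > nSamples)) return("schedule interval outside recording")
  if (any(s >= e)) return("schedule intervals must satisfy start < end")
  if (is.unsorted(s)) return("schedule intervals must be sorted by start")
  if (nrow(schedule) > 1L && any(e[-nrow(schedule)] > s[-1L]))
    return("schedule intervals overlap")
  TRUE
}

setValidity("EMGRecording", function(object) {
  if (!is.numeric(object@samples)) return("samples must be numeric")
  if (nrow(object@samples) < 1L || ncol(object@samples) < 1L)
    return("need at least one channel and one sample")
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be a positive scalar")
  validSchedule(object@schedule, ncol(object@samples))
})

#' Construct an EMGRecording
#'
#' @param samples numeric matrix, channels x n_samples (millivolts).
#' @param fs sampling rate (Hz).
#' @param schedule movement schedule `data.frame` with columns `class`,
#'   `start`, `end` (0-based, half-open sample intervals).
#' @param subjectId opaque subject identifier.
#' @return An [EMGRecording-class] object.
#' @examples
#' rec <- EMGRecording(matrix(rnorm(200), 2), fs = 100,
#'                     schedule = data.frame(class = "open hand",
#'                                           start = 0L, end = 100L))
#' nChannels(rec)
#' @export
EMGRecording <- function(samples, fs, schedule = emptySchedule(),
                         subjectId = "subject") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  schedule$start <- as.integer(schedule$start)
  schedule$end <- as.integer(schedule$end)
  new("EMGRecording", samples = samples, fs = as.numeric(fs),
      subjectId = subjectId, schedule = schedule)
}

#' @rdname EMGRecording
#' @export
emptySchedule <- function() {
  data.frame(class = character(), start = integer(), end = integer())
}

#' @rdname EMGRecording-class
setMethod("samples", "EMGRecording", function(x) x@samples)
#' @rdname EMGRecording-class
setMethod("samplingRate", "EMGRecording", function(x) x@fs)
#' @rdname EMGRecording-class
setMethod("subjectId", "EMGRecording", function(x) x@subjectId)
#' @rdname EMGRecording-class
setMethod("schedule", "EMGRecording", function(x) x@schedule)
#' @rdname EMGRecording-class
setMethod("nChannels", "EMGRecording", function(x) nrow(x@samples))

setMethod("show", "EMGRecording", function(object) {
  cat("EMGRecording:", nrow(object@samples), "channel(s) x",
      ncol(object@samples), "samples @", object@fs, "Hz\n")
  cat("  subject:", object@subjectId, "\n")
  cat("  schedule:", nrow(object@schedule), "entries,",
      length(unique(object@schedule$class)), "classes\n")
})

#' Labelled analysis windows cut from a recording
#'
#' Fixed-length windows (default 200 ms, 100 ms hop) lying entirely within a
#' single movement-schedule entry.  Stored as a channels x N x w array.
#'
#' @slot windows numeric array, channels x N x w.
#' @slot labels class label per window.
#' @slot entry index of the schedule entry each window came from.
#' @slot step hop size in samples.
#' @slot fs sampling rate (Hz).
#'
#' @param x an `EMGWindowSet` (accessors).
#' @param i window index for `windowData`, returning a channels x N matrix.
#' @aliases windowData nWindows windowLength windowLabels
#' @export
setClass("EMGWindowSet",
  representation(windows = "array", labels = "character", entry = "integer",
                 step = "integer", fs = "numeric"))

setValidity("EMGWindowSet", function(object) {
  d <- dim(object@windows)
  if (length(d) != 3L) return("windows must be a 3-d array (channels x N x w)")
  if (length(object@labels) != d[3L]) return("one label per window required")
  if (length(object@entry) != d[3L]) return("one entry index per window required")
  if (object@fs <= 0) return("fs must be positive")
  TRUE
})

#' @rdname EMGWindowSet-class
setMethod("nWindows", "EMGWindowSet", function(x) dim(x@windows)[3L])
#' @rdname EMGWindowSet-class
setMethod("windowLength", "EMGWindowSet", function(x) dim(x@windows)[2L])
#' @rdname EMGWindowSet-class
setMethod("nChannels", "EMGWindowSet", function(x) dim(x@windows)[1L])
#' @rdname EMGWindowSet-class
setMethod("windowLabels", "EMGWindowSet", function(x) x@labels)
#' @rdname EMGWindowSet-class
setMethod("windowData", "EMGWindowSet", function(x, i) x@windows[, , i, drop = TRUE])
#' @rdname EMGWindowSet-class
setMethod("samplingRate", "EMGWindowSet", function(x) x@fs)

setMethod("show", "EMGWindowSet", function(object) {
  d <- dim(object@windows)
  cat("EMGWindowSet:", d[3L], "windows of", d[2L], "samples x", d[1L],
      "channel(s) @", object@fs, "Hz (hop", object@step, "samples)\n")
  tab <- table(object@labels)
  cat("  classes:", paste0(names(tab), " (", as.integer(tab), ")",
                           collapse = ", "), "\n")
})

#' Window-level feature matrix
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with one assay `"features"` (features x windows), feature annotation in
#' `rowData` (`block`, `feature`, `index`) and window annotation in `colData`
#' (`label`, `entry`).  `featureValues()` returns the conventional windows x
#' features matrix used by the classifiers; column names follow the
#' deterministic `block.feature.index` scheme used by the CSV writer.
#'
#' @param x an `EMGFeatureMatrix` (accessors).
#' @aliases featureValues featureInfo
#' @export
setClass("EMGFeatureMatrix", contains = "SummarizedExperiment")

#' Construct an EMGFeatureMatrix
#'
#' @param values numeric matrix, windows x features.
#' @param info `data.frame` with columns `block`, `feature`, `index`
#'   describing each feature column.
#' @param labels class label per window.
#' @param entry optional schedule-entry index per window.
#' @return An [EMGFeatureMatrix-class].
#' @export
EMGFeatureMatrix <- function(values, info, labels,
                             entry = rep(NA_integer_, length(labels))) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(info))
    stop("feature info must describe every column of `values`")
  if (nrow(values) != length(labels))
    stop("one label per window (row) required")
  ids <- featureIds(info)
  if (anyDuplicated(ids)) stop("duplicated feature identifiers")
  assay <- t(values)
  rownames(assay) <- ids
  se <- SummarizedExperiment(
    assays = list(features = assay),
    rowData = DataFrame(block = info$block, feature = info$feature,
                        index = info$index),
    colData = DataFrame(label = labels, entry = entry))
  new("EMGFeatureMatrix", se)
}

featureIds <- function(info) paste(info$block, info$feature, info$index, sep = ".")

#' @rdname EMGFeatureMatrix-class
setMethod("featureValues", "EMGFeatureMatrix", function(x) t(assay(x, "features")))
#' @rdname EMGFeatureMatrix-class
setMethod("featureInfo", "EMGFeatureMatrix",
          function(x) as.data.frame(rowData(x)))
#' @rdname EMGFeatureMatrix-class
setMethod("windowLabels", "EMGFeatureMatrix", function(x) colData(x)$label)
#' @rdname EMGFeatureMatrix-class
setMethod("nWindows", "EMGFeatureMatrix", function(x) ncol(x))

setMethod("show", "EMGFeatureMatrix", function(object) {
  cat("EMGFeatureMatrix:", ncol(object), "windows x", nrow(object),
      "features\n")
  cat("  blocks:", paste(unique(rowData(object)$block), collapse = ", "), "\n")
  tab <- table(colData(object)$label)
  cat("  classes:", length(tab), "\n")
})
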