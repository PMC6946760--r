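# Minimal RIFF/WAVE reader and writer (PCM16 and IEEE float32, any channel
# count).  Written in-package because waveform containers are the natural
# interchange for EMG; only the chunks needed for that purpose are handled.

readWavFile <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; dataRaw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        nChannels   = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sampleRate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bitsPerSample = readBin(body[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      dataRaw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(dataRaw)) break
  }
  if (is.null(fmt) || is.null(dataRaw)) stop("malformed WAV: missing fmt or data chunk")
  nc <- fmt$nChannels
  if (fmt$audioFormat == 3L && fmt$bitsPerSample == 32L) {
    x <- readBin(dataRaw, "double", length(dataRaw) %/% 4L, size = 4,
                 endian = "little")
  } else if (fmt$audioFormat == 1L && fmt$bitsPerSample == 16L) {
    x <- readBin(dataRaw, "integer", length(dataRaw) %/% 2L, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else {
    stop("unsupported WAV encoding (need PCM16 or float32)")
  }
  n <- length(x) %/% nc
  # interleaved frames -> channels x samples
  list(samples = matrix(x[seq_len(n * nc)], nrow = nc),
       fs = fmt$sampleRate)
}

writeWavFile <- function(samples, fs, path) {
  nc <- nrow(samples); n <- ncol(samples)
  dataSize <- 4L * nc * n
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")           # IEEE float
  writeBin(as.integer(nc), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * nc * 4L), con, size = 4, endian = "little")
  writeBin(as.integer(nc * 4L), con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  writeBin(as.vector(samples), con, size = 4, endian = "little")
  invisible(path)
}
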