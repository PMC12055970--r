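# File I/O for the pipeline's external formats: multi-page grayscale TIFF
# for video (via the tiff package) and 32-bit float WAV for hydrophone
# pressure traces. WAV samples are pressure in pascal with unit sensitivity,
# so no calibration chain is needed downstream; the RIFF reader/writer below
# is deliberately minimal (PCM-float mono only).

#' Write a video sequence as a multi-page 8-bit grayscale TIFF
#'
#' @param video a [video_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(video, path) {
  stopifnot(inherits(video, "video_sequence"))
  pages <- lapply(seq_len(n_frames(video)),
                  function(k) video$frames[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read a multi-page grayscale TIFF into a video sequence
#'
#' @param path TIFF file path.
#' @param frame_rate frames per second.
#' @param pixel_pitch_um pixel pitch in micrometres per pixel.
#' @param exposure exposure time in seconds.
#' @param time_offset time of the first frame relative to the trigger, s.
#' @return a [video_sequence()].
#' @export
read_video_tiff <- function(path, frame_rate = 1e5, pixel_pitch_um = 25,
                            exposure = 0.357e-6, time_offset = 0) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]   # collapse grayscale channels
    frames[, , k] <- as.integer(round(pg * 255))
  }
  video_sequence(frames, frame_rate = frame_rate,
                 pixel_pitch_um = pixel_pitch_um, exposure = exposure,
                 time_offset = time_offset)
}

#' Write an audio trace as 32-bit float WAV
#'
#' Samples are stored as IEEE float pascal (hydrophone sensitivity folded in
#' upstream). The trigger index is not representable in WAV and travels in
#' the ground-truth/manifest JSON instead.
#'
#' @param audio an [audio_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_audio_wav <- function(audio, path) {
  stopifnot(inherits(audio, "audio_trace"))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(audio$samples)
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")              # IEEE float
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(audio$fs), con, size = 4, endian = "little")
  writeBin(as.integer(audio$fs * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(audio$samples, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a 32-bit float mono WAV into an audio trace
#'
#' @param path WAV file path.
#' @param trigger_sample 1-based index of the sample defining t = 0.
#' @return an [audio_trace()].
#' @export
read_audio_wav <- function(path, trigger_sample = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fs <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 3L) stop("only IEEE-float WAV supported")
      if (fmt[2] != 1L) stop("only mono WAV supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, raw(), n = sz - 8L)
    } else if (id == "data") {
      samples <- readBin(con, numeric(), n = sz %/% 4L, size = 4,
                         endian = "little")
    } else {
      readBin(con, raw(), n = sz)
    }
    if (!is.null(fs) && !is.null(samples)) break
  }
  if (is.null(fs) || is.null(samples)) stop("incomplete WAV file: ", path)
  audio_trace(samples, fs = fs, trigger_sample = trigger_sample)
}
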