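# Core data containers. Conventions used throughout:
#   - frames are integer arrays [row, col, frame], 8-bit grayscale 0..255;
#     row 0-offset top of frame, y = +columns (rightward, mm),
#     z = -rows (upward, mm)
#   - all time axes are trigger-aligned: t = 0 is the oscilloscope trigger,
#     which coincides with the needle's far-end stop after firing

#' Calibrated high-speed video sequence
#'
#' @param frames integer array `[rows, cols, T]` of 8-bit grayscale
#'   intensities (0 = black). Shadowgraphy convention: the needle and
#'   bubbles are dark on a bright background.
#' @param frame_rate frames per second (default 100 000, the recording rate).
#' @param pixel_pitch_um optical scaling in micrometres per pixel (default 25).
#' @param exposure exposure time per frame, s.
#' @param time_offset time of the first frame relative to the trigger, s
#'   (negative when recording starts before the trigger).
#' @return object of class `video_sequence`.
#' @export
video_sequence <- function(frames, frame_rate = 1e5, pixel_pitch_um = 25,
                           exposure = 0.357e-6, time_offset = 0) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L, dim(frames)[3] >= 1L,
            frame_rate > 0, pixel_pitch_um > 0)
  storage.mode(frames) <- "integer"
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_pitch_um = pixel_pitch_um, exposure = exposure,
                 time_offset = time_offset),
            class = "video_sequence")
}

#' @export
dim.video_sequence <- function(x) dim(x$frames)

#' Number of frames in a video sequence
#' @param video a [video_sequence()].
#' @export
n_frames <- function(video) dim(video$frames)[3]

#' Trigger-aligned frame times of a video sequence
#' @param video a [video_sequence()].
#' @return numeric vector of times in seconds, one per frame.
#' @export
frame_times <- function(video) {
  video$time_offset + (seq_len(n_frames(video)) - 1L) / video$frame_rate
}

#' @export
print.video_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Video sequence: %d frames of %d x %d px @ %g fps\n",
              d[3], d[1], d[2], x$frame_rate))
  cat(sprintf("  pixel pitch %g um, exposure %g s, first frame at t = %g s\n",
              x$pixel_pitch_um, x$exposure, x$time_offset))
  invisible(x)
}

#' Calibrated hydrophone pressure trace
#'
#' @param samples numeric vector of pressure in Pa.
#' @param fs sampling rate in Hz (default 100 000).
#' @param trigger_sample 1-based index of the sample at which the
#'   oscilloscope triggered; that sample defines t = 0.
#' @return object of class `audio_trace`.
#' @export
audio_trace <- function(samples, fs = 1e5, trigger_sample = 1L) {
  stopifnot(is.numeric(samples), length(samples) >= 1L, fs > 0)
  trigger_sample <- as.integer(trigger_sample)
  if (trigger_sample < 1L || trigger_sample > length(samples)) {
    stop("trigger_sample outside the trace")
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 trigger_sample = trigger_sample,
                 duration = length(samples) / fs),
            class = "audio_trace")
}

#' Trigger-aligned sample times of an audio trace
#' @param audio an [audio_trace()].
#' @export
sample_times <- function(audio) {
  (seq_along(audio$samples) - audio$trigger_sample) / audio$fs
}

#' @export
print.audio_trace <- function(x, ...) {
  cat(sprintf(
    "Audio trace: %d samples @ %g Hz (%.4g s), trigger at sample %d\n",
    length(x$samples), x$fs, x$duration, x$trigger_sample))
  cat(sprintf("  rms %.4g Pa (%.1f dB re 1 uPa)\n",
              sqrt(mean(x$samples^2)), band_spl(x$samples)))
  invisible(x)
}

#' Projected bubble area time series
#'
#' @param times trigger-aligned times, s.
#' @param areas projected areas, mm2 (non-negative).
#' @param n_clamped number of frames whose raw dark-pixel difference was
#'   negative and clamped to zero (QC information).
#' @return object of class `area_series`.
#' @export
area_series <- function(times, areas, n_clamped = 0L) {
  stopifnot(length(times) == length(areas), all(areas >= 0))
  structure(list(times = as.numeric(times), areas = as.numeric(areas),
                 n_clamped = as.integer(n_clamped)),
            class = "area_series")
}

#' @export
print.area_series <- function(x, ...) {
  cat(sprintf("Area series: %d points, t in [%.4g, %.4g] s\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  max %.4g mm2 at t = %.4g s", max(x$areas),
              x$times[which.max(x$areas)]))
  if (x$n_clamped > 0) cat(sprintf("  (%d frames clamped)", x$n_clamped))
  cat("\n")
  invisible(x)
}

#' @export
plot.area_series <- function(x, ...) {
  graphics::plot(x$times * 1e3, x$areas, type = "l",
                 xlab = "time after trigger (ms)",
                 ylab = expression(paste("projected bubble area (", mm^2, ")")),
                 ...)
  invisible(x)
}
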