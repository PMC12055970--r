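# Projected bubble-area estimation from shadowgraphy video: binarize each
# frame, count dark pixels, subtract the dark-pixel count of the needle at
# rest, convert to mm2 through the pixel pitch. This reproduces the
# published estimator literally: the rest-needle count is subtracted even
# while the needle moves, so displaced-needle pixels can inflate the
# estimate; an optional exclusion mode masking a tracked silhouette is
# provided as a clearly labelled extension.

#' Binarize a grayscale frame (dark = foreground)
#'
#' Pixels strictly below the threshold map to `TRUE`. With `method =
#' "otsu"` the threshold is computed by Otsu's criterion (via
#' \pkg{EBImage}); with `method = "fixed"` the supplied `level` is used.
#'
#' @param frame numeric or integer matrix of 8-bit intensities.
#' @param method `"otsu"` or `"fixed"`.
#' @param level threshold for `method = "fixed"`, on the 0-255 scale.
#' @return logical matrix with attribute `threshold`.
#' @export
binarize_frame <- function(frame, method = c("otsu", "fixed"), level = 128) {
  method <- match.arg(method)
  stopifnot(is.matrix(frame), length(frame) > 0)
  thr <- if (method == "otsu") {
    if (diff(range(frame)) == 0) {
      stop("constant-intensity frame: Otsu threshold undefined; ",
           "use method = \"fixed\" with an explicit level")
    }
    EBImage::otsu(frame / 255) * 255
  } else {
    level
  }
  structure(frame < thr, threshold = thr)
}

#' Build the needle-at-rest reference mask
#'
#' Binarizes one or more pre-firing frames and takes the pixelwise majority
#' vote, removing salt noise. The reference carries the dark-pixel count
#' subtracted by the area estimator and the threshold to reuse for the
#' moving frames (held fixed so bubble appearance cannot drift it).
#'
#' @param rest_frames a single matrix or a list of grayscale frames showing
#'   the needle at rest.
#' @inheritParams binarize_frame
#' @return object of class `needle_rest_reference` with fields `rest_mask`,
#'   `rest_dark_count` and `threshold`.
#' @export
build_rest_reference <- function(rest_frames, method = c("otsu", "fixed"),
                                 level = 128) {
  method <- match.arg(method)
  if (is.matrix(rest_frames)) rest_frames <- list(rest_frames)
  if (!length(rest_frames)) stop("need at least one rest frame")
  masks <- lapply(rest_frames, binarize_frame, method = method, level = level)
  votes <- Reduce(`+`, lapply(masks, function(m) m + 0L))
  mask <- votes >= (length(masks) + 1) / 2
  structure(list(rest_mask = mask,
                 rest_dark_count = sum(mask),
                 threshold = attr(masks[[1]], "threshold"),
                 n_frames = length(masks)),
            class = "needle_rest_reference")
}

#' @export
print.needle_rest_reference <- function(x, ...) {
  cat(sprintf(
    "Needle rest reference: %d dark px of %d x %d (threshold %.1f, %d frames)\n",
    x$rest_dark_count, nrow(x$rest_mask), ncol(x$rest_mask), x$threshold,
    x$n_frames))
  invisible(x)
}

#' Projected bubble area as a function of time
#'
#' For each frame, the area is `max(0, dark_count - rest_dark_count) *
#' pitch_mm^2`: the number of dark pixels in excess of the needle-at-rest
#' count, converted to mm2. The rest reference's threshold is reused for
#' every frame. Negative differences (needle partially leaving the frame)
#' are clamped to zero and counted in the `n_clamped` QC field.
#'
#' @param video a [video_sequence()].
#' @param ref a [build_rest_reference()] result with matching frame size.
#' @param exclude_needle experimental extension (not the published rule):
#'   when `TRUE`, dark pixels inside the dilated rest mask are excluded
#'   from the count instead of subtracting the rest count, removing the
#'   moving-needle bias at the price of dropping bubbles that overlap the
#'   rest silhouette.
#' @return an [area_series()].
#' @export
bubble_area_series <- function(video, ref, exclude_needle = FALSE) {
  stopifnot(inherits(video, "video_sequence"),
            inherits(ref, "needle_rest_reference"))
  d <- dim(video$frames)
  if (d[1] != nrow(ref$rest_mask) || d[2] != ncol(ref$rest_mask)) {
    stop(sprintf("frame size %d x %d does not match reference %d x %d",
                 d[1], d[2], nrow(ref$rest_mask), ncol(ref$rest_mask)))
  }
  px_mm2 <- (video$pixel_pitch_um / 1000)^2
  thr <- ref$threshold
  nf <- d[3]
  raw <- numeric(nf)
  for (k in seq_len(nf)) {
    dark <- video$frames[, , k] < thr
    raw[k] <- if (exclude_needle) {
      sum(dark & !ref$rest_mask)
    } else {
      sum(dark) - ref$rest_dark_count
    }
  }
  area_series(frame_times(video), pmax(0, raw) * px_mm2,
              n_clamped = sum(raw < 0))
}

#' Summarize an area series
#'
#' @param series an [area_series()].
#' @param area_threshold area above which a frame counts towards the
#'   cavitation duration, mm2. The default 0 counts any nonzero area.
#' @return list of class `area_summary` with `max_area` (mm2),
#'   `time_of_max` (s) and `duration` (s, total time with area above the
#'   threshold).
#' @export
summarize_area <- function(series, area_threshold = 0) {
  stopifnot(inherits(series, "area_series"), length(series$times) >= 1)
  dt <- if (length(series$times) > 1) diff(series$times[1:2]) else 0
  structure(list(max_area = max(series$areas),
                 time_of_max = series$times[which.max(series$areas)],
                 duration = sum(series$areas > area_threshold) * dt,
                 area_threshold = area_threshold),
            class = "area_summary")
}

#' @export
print.area_summary <- function(x, ...) {
  cat(sprintf("Max area %.4g mm2 at t = %.4g s; duration above %g mm2: %.4g ms\n",
              x$max_area, x$time_of_max, x$area_threshold, x$duration * 1e3))
  invisible(x)
}

#' Bundle replicate area series for aggregation
#'
#' The published aggregation pools N = n_devices x n_replicates recordings
#' (N = 9 from 3 devices x 3 technical replicates) on a common time grid.
#'
#' @param series list of [area_series()] sharing one time grid.
#' @param device_ids,replicate_ids identifiers, recycled to `length(series)`.
#' @return object of class `replicate_ensemble`.
#' @export
replicate_ensemble <- function(series, device_ids = seq_along(series),
                               replicate_ids = rep(1L, length(series))) {
  stopifnot(length(series) >= 1,
            all(vapply(series, inherits, logical(1), "area_series")))
  grid <- series[[1]]$times
  for (s in series[-1]) {
    if (length(s$times) != length(grid) ||
        max(abs(s$times - grid)) > 1e-12) {
      stop("series are not on a common time grid; resample before pooling")
    }
  }
  structure(list(series = series, times = grid,
                 device_ids = rep_len(device_ids, length(series)),
                 replicate_ids = rep_len(replicate_ids, length(series))),
            class = "replicate_ensemble")
}

#' Pointwise mean and standard deviation across replicates
#'
#' @param ensemble a [replicate_ensemble()] of at least two series.
#' @return data frame with `time`, `mean_area` and `sd_area` (sample SD,
#'   denominator N - 1), one row per grid point.
#' @export
aggregate_replicates <- function(ensemble) {
  stopifnot(inherits(ensemble, "replicate_ensemble"))
  if (length(ensemble$series) < 2) stop("need at least two replicate series")
  m <- vapply(ensemble$series, function(s) s$areas,
              numeric(length(ensemble$times)))
  data.frame(time = ensemble$times,
             mean_area = rowMeans(m),
             sd_area = apply(m, 1, stats::sd))
}

#' Maximum distance of bubble pixels from the needle silhouette
#'
#' Binarizes a frame with the reference threshold, removes the rest-needle
#' mask, and returns the largest Euclidean distance (in mm, via the pixel
#' pitch) from any remaining dark pixel to the needle silhouette — the
#' spatial reach of the cavitation cloud from the cut.
#'
#' @param frame grayscale matrix.
#' @param ref a [build_rest_reference()] result.
#' @param pixel_pitch_um optical scaling, um per pixel.
#' @return distance in mm (0 when no bubble pixels are present).
#' @export
max_bubble_distance <- function(frame, ref, pixel_pitch_um = 25) {
  stopifnot(inherits(ref, "needle_rest_reference"))
  bubble <- (frame < ref$threshold) & !ref$rest_mask
  if (!any(bubble)) return(0)
  bg <- matrix(1, nrow(frame), ncol(frame))
  bg[ref$rest_mask] <- 0
  d <- EBImage::distmap(bg)
  max(d[bubble]) * pixel_pitch_um / 1000
}
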