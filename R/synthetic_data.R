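# Ground-truthed synthetic recordings emulating the experiment: a dark
# needle silhouette firing through a backlit frame (shadowgraphy), transient
# dark bubble clouds with analytically known projected areas, and hydrophone
# traces mixing broadband bursts with decaying ringing tones.
#
# Physical frame coordinates: y (mm) = +columns rightward from the left
# frame edge, z (mm) = -rows downward from the top edge (so z is negative
# inside the frame and increases upward). Pixel centres sit at
# (col - 0.5) * pitch, -(row - 0.5) * pitch.

#' Prescribe a transient bubble event
#'
#' A bubble is an ellipse with semi-axes `a` (along y) and `b` (along z),
#' alive on `[birth_time, death_time)`. Its true projected area at time t is
#' `pi * a(t) * b(t)`, reduced by the clipped fraction if the ellipse
#' crosses the frame boundary. Semi-axes may be constants (mm) or functions
#' of time returning mm, enabling growth/collapse profiles.
#'
#' @param center_y,center_z centre position in mm (frame coordinates).
#' @param a,b semi-axes in mm, numeric or `function(t)`.
#' @param birth_time,death_time lifetime bounds in s (trigger-aligned);
#'   bubble lifetimes in the recordings are of order 0.1-1 ms.
#' @return object of class `bubble_event`.
#' @export
bubble_event <- function(center_y, center_z, a, b = a,
                         birth_time, death_time) {
  stopifnot(death_time > birth_time)
  structure(list(center_y = center_y, center_z = center_z, a = a, b = b,
                 birth_time = birth_time, death_time = death_time),
            class = "bubble_event")
}

axis_at <- function(ax, t) if (is.function(ax)) ax(t) else ax

#' Default firing motion profile for the synthetic needle
#'
#' Longitudinal (z) travel decelerating into an abrupt stop at `stop_time`,
#' followed by a decaying lateral (y) flexural oscillation — the motion
#' signature that drives hydrodynamic cavitation in the recordings. The
#' defaults give a peak lateral tip velocity of
#' `2 * pi * lateral_freq * lateral_amp_mm / 1000` m/s (about 7.5 m/s).
#'
#' @param stop_time time of the far-end stop, s (trigger-aligned).
#' @param travel_mm longitudinal travel before the stop, mm (downward).
#' @param travel_duration duration of the longitudinal stroke, s.
#' @param lateral_amp_mm amplitude of the post-stop lateral oscillation, mm.
#' @param lateral_freq frequency of the lateral oscillation, Hz.
#' @param lateral_decay exponential decay time constant of the oscillation, s.
#' @return list with displacement functions `y(t)` and `z(t)` in mm.
#' @export
firing_motion_profile <- function(stop_time = 0.025, travel_mm = 3,
                                  travel_duration = 0.004,
                                  lateral_amp_mm = 0.3, lateral_freq = 4000,
                                  lateral_decay = 0.003) {
  t0 <- stop_time - travel_duration
  zfun <- function(t) {
    s <- pmin(pmax((t - t0) / travel_duration, 0), 1)
    -travel_mm * (s * s * (3 - 2 * s))       # smoothstep: still at both ends
  }
  yfun <- function(t) {
    dt <- t - stop_time
    ifelse(dt > 0,
           lateral_amp_mm * sin(2 * pi * lateral_freq * dt) *
             exp(-dt / lateral_decay),
           0)
  }
  list(y = yfun, z = zfun)
}

#' Describe a synthetic shadowgraphy scene
#'
#' Defaults reproduce the recording conditions: 384 x 288 px frames at
#' 100 000 frames/s, 25 um/pixel, 8-bit intensities with bright background
#' (about 220), dark needle and bubbles (about 30) and Gaussian noise
#' (SD 5), so that the dark/bright margin is 38 noise SDs and binarization
#' is unambiguous.
#'
#' @param needle_geometry `"side_cut"` (lancet + bevel, sharp point on the
#'   right edge of the shaft) or `"front_cut"` (symmetric Franseen-like
#'   crown, point on the axis).
#' @param motion_profile list of displacement functions `y(t)`, `z(t)` in mm
#'   added to the rest tip position; see [firing_motion_profile()].
#' @param bubble_events list of [bubble_event()]s.
#' @param duration scene length in s.
#' @param frame_rate frames per second.
#' @param pixel_pitch_um um per pixel.
#' @param frame_size `c(rows, cols)`.
#' @param intensity_model list with `background`, `needle`, `bubble`
#'   (8-bit levels) and `noise_sd`.
#' @param tip_rest_y,tip_rest_z rest position of the needle tip apex, mm.
#' @param half_width_mm needle shaft half width, mm (14 G outer diameter
#'   2.109 mm by default).
#' @param taper_mm length of the tip taper, mm.
#' @param tilt_deg small tilt of the needle axis from the vertical, degrees
#'   (realistic mounting misalignment; also decorrelates boundary
#'   rasterization across rows).
#' @param time_offset time of the first frame relative to the trigger, s.
#' @param allow_needle_overlap if `FALSE` (default) bubbles intersecting the
#'   needle silhouette are rejected, because the area estimator cannot
#'   separate them; set `TRUE` only for robustness experiments.
#' @param seed integer seed driving all stochastic draws.
#' @return object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(needle_geometry = c("side_cut", "front_cut"),
                            motion_profile = firing_motion_profile(),
                            bubble_events = list(),
                            duration = 0.003,
                            frame_rate = 1e5,
                            pixel_pitch_um = 25,
                            frame_size = c(288L, 384L),
                            intensity_model = list(background = 220,
                                                   needle = 30, bubble = 30,
                                                   noise_sd = 5),
                            tip_rest_y = 4.8, tip_rest_z = -1.5,
                            half_width_mm = 2.109 / 2, taper_mm = 1.5,
                            tilt_deg = 1.5,
                            time_offset = 0,
                            allow_needle_overlap = FALSE,
                            seed = 1L) {
  needle_geometry <- match.arg(needle_geometry)
  stopifnot(frame_rate > 0, pixel_pitch_um > 0, duration > 0,
            length(frame_size) == 2L, all(frame_size >= 8L),
            half_width_mm > 0, taper_mm > 0)
  im <- intensity_model
  stopifnot(all(c("background", "needle", "bubble", "noise_sd") %in% names(im)))
  if (im$bubble >= im$background - 5 * im$noise_sd) {
    stop("bubble intensity too bright: must sit below background by > 5 SD ",
         "for the shadowgraphy binarizer to succeed")
  }
  if (!is.list(motion_profile) ||
      !all(c("y", "z") %in% names(motion_profile)) ||
      !is.function(motion_profile$y) || !is.function(motion_profile$z)) {
    stop("motion_profile must be a list of functions y(t), z(t)")
  }
  structure(list(needle_geometry = needle_geometry,
                 motion_profile = motion_profile,
                 bubble_events = bubble_events,
                 duration = duration, frame_rate = frame_rate,
                 pixel_pitch_um = pixel_pitch_um,
                 frame_size = as.integer(frame_size),
                 intensity_model = im,
                 tip_rest_y = tip_rest_y, tip_rest_z = tip_rest_z,
                 half_width_mm = half_width_mm, taper_mm = taper_mm,
                 tilt_deg = tilt_deg,
                 time_offset = time_offset,
                 allow_needle_overlap = allow_needle_overlap,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

# Needle silhouette mask. The needle hangs from the top edge; its lower
# boundary z_bottom(y) is slanted (side cut bevel, apex at the right shaft
# edge) or a symmetric vee (front cut crown, apex on the axis).
needle_bottom_profile <- function(y, geometry, tip_y, tip_z, hw, taper) {
  if (geometry == "side_cut") {
    tip_z + taper * (tip_y + hw - y) / (2 * hw)
  } else {
    tip_z + taper * abs(y - tip_y) / hw
  }
}

render_needle_mask <- function(rows, cols, pitch_mm, geometry,
                               tip_y, tip_z, hw, taper, tilt_deg = 0) {
  ycol <- (seq_len(cols) - 0.5) * pitch_mm
  zrow <- -(seq_len(rows) - 0.5) * pitch_mm
  # coordinates relative to the (possibly tilted) needle axis: the axis
  # passes through the tip reference and leans by tilt_deg from vertical
  slope <- tanpi(tilt_deg / 180)
  yrel <- outer(-slope * (zrow - tip_z), ycol - tip_y, "+")   # y - axis(z)
  zb <- needle_bottom_profile(yrel + tip_y, geometry, tip_y, tip_z, hw, taper)
  mask <- (abs(yrel) <= hw) & (matrix(zrow, rows, cols) >= zb)
  mask
}

# Tip apex in physical coordinates for the ground-truth trajectory.
needle_tip_point <- function(geometry, tip_y, tip_z, hw) {
  if (geometry == "side_cut") c(y = tip_y + hw, z = tip_z)
  else c(y = tip_y, z = tip_z)
}

# Area-exact ellipse rasterization over the bounding box: pixels are
# ranked by subsampled coverage and included, fully-covered ones first,
# until the rendered pixel count matches `target_px` (the analytic clipped
# area in pixel units). The silhouette stays disc-shaped while its binary
# projected area equals the prescribed ground truth to within half a
# pixel, so lattice artifacts do not contaminate estimator benchmarks.
render_ellipse <- function(mask, pitch_mm, cy, cz, a, b, target_px,
                           ss = 8L) {
  rows <- nrow(mask); cols <- ncol(mask)
  c_lo <- max(1L, floor((cy - a) / pitch_mm - 1)); c_hi <- min(cols, ceiling((cy + a) / pitch_mm + 1))
  r_lo <- max(1L, floor((-cz - b) / pitch_mm - 1)); r_hi <- min(rows, ceiling((-cz + b) / pitch_mm + 1))
  if (c_lo > c_hi || r_lo > r_hi) return(mask)
  off <- ((seq_len(ss) - 0.5) / ss - 0.5) * pitch_mm
  cov <- matrix(0L, r_hi - r_lo + 1L, c_hi - c_lo + 1L)
  yc <- (seq(c_lo, c_hi) - 0.5) * pitch_mm
  zc <- -(seq(r_lo, r_hi) - 0.5) * pitch_mm
  for (oy in off) for (oz in off) {
    u <- (yc + oy - cy) / a
    v <- (zc + oz - cz) / b
    cov <- cov + (outer(v^2, u^2, "+") <= 1)
  }
  ord <- order(cov, decreasing = TRUE)
  n_add <- min(round(target_px), sum(cov > 0))
  sub <- mask[r_lo:r_hi, c_lo:c_hi]
  sub[ord[seq_len(n_add)]] <- TRUE
  mask[r_lo:r_hi, c_lo:c_hi] <- sub
  mask
}

# Analytic projected area of an ellipse clipped to the frame, mm2.
# Column-wise 1-D integration of the clipped z-extent.
clipped_ellipse_area <- function(cy, cz, a, b, width_mm, height_mm,
                                 n_grid = 2000L) {
  y_lo <- max(cy - a, 0); y_hi <- min(cy + a, width_mm)
  if (y_lo >= y_hi) return(0)
  y <- seq(y_lo, y_hi, length.out = n_grid)
  dy <- (y_hi - y_lo) / (n_grid - 1)
  h <- b * sqrt(pmax(0, 1 - ((y - cy) / a)^2))
  z_top <- pmin(cz + h, 0); z_bot <- pmax(cz - h, -height_mm)
  widths <- pmax(0, z_top - z_bot)
  sum((widths[-1] + widths[-n_grid]) / 2) * dy
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic high-speed video with ground truth
#'
#' Renders the scene frame by frame: bright background, dark needle
#' silhouette following the motion profile, dark elliptical bubbles, plus
#' Gaussian pixel noise. Identical scenes (including seed) yield
#' bit-identical output.
#'
#' @param scene a [synthetic_scene()].
#' @return list with `video` (a [video_sequence()]) and `truth`, a data frame
#'   with one row per frame: `time`, analytic `area_mm2` (sum over live
#'   events, clipped to the frame), and the needle tip apex position
#'   (`tip_row`, `tip_col`, sub-pixel, 1-based; `tip_y_mm`, `tip_z_mm`).
#' @export
generate_video <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  rows <- scene$frame_size[1]; cols <- scene$frame_size[2]
  pitch <- scene$pixel_pitch_um / 1000
  width_mm <- cols * pitch; height_mm <- rows * pitch
  nf <- ceiling(scene$duration * scene$frame_rate)
  times <- scene$time_offset + (seq_len(nf) - 1L) / scene$frame_rate
  im <- scene$intensity_model

  # validate bubbles: a fully out-of-frame event is a scene error
  for (i in seq_along(scene$bubble_events)) {
    ev <- scene$bubble_events[[i]]
    tmid <- (ev$birth_time + ev$death_time) / 2
    a <- axis_at(ev$a, tmid); b <- axis_at(ev$b, tmid)
    if (ev$center_y + a <= 0 || ev$center_y - a >= width_mm ||
        ev$center_z + b <= -height_mm || ev$center_z - b >= 0) {
      stop(sprintf("bubble event %d lies fully outside the frame", i))
    }
  }

  frames <- array(0L, dim = c(rows, cols, nf))
  truth <- data.frame(frame = seq_len(nf), time = times, area_mm2 = 0,
                      tip_row = NA_real_, tip_col = NA_real_,
                      tip_y_mm = NA_real_, tip_z_mm = NA_real_)

  with_local_seed(scene$seed, {
    for (k in seq_len(nf)) {
      t <- times[k]
      tip_y <- scene$tip_rest_y + scene$motion_profile$y(t)
      tip_z <- scene$tip_rest_z + scene$motion_profile$z(t)
      needle <- render_needle_mask(rows, cols, pitch, scene$needle_geometry,
                                   tip_y, tip_z, scene$half_width_mm,
                                   scene$taper_mm, scene$tilt_deg)
      tip <- needle_tip_point(scene$needle_geometry, tip_y, tip_z,
                              scene$half_width_mm)
      if (tip["y"] < 0 || tip["y"] > width_mm ||
          tip["z"] > 0 || tip["z"] < -height_mm) {
        stop(sprintf("needle tip exits the frame at t = %g s", t))
      }
      bubbles <- matrix(FALSE, rows, cols)
      area <- 0
      for (i in seq_along(scene$bubble_events)) {
        ev <- scene$bubble_events[[i]]
        if (t >= ev$birth_time && t < ev$death_time) {
          a <- axis_at(ev$a, t); b <- axis_at(ev$b, t)
          ev_area <- clipped_ellipse_area(ev$center_y, ev$center_z, a, b,
                                          width_mm, height_mm)
          bubbles <- render_ellipse(bubbles, pitch, ev$center_y, ev$center_z,
                                    a, b, target_px = ev_area / pitch^2)
          area <- area + ev_area
        }
      }
      if (!scene$allow_needle_overlap && any(bubbles & needle)) {
        stop(sprintf(
          "bubble overlaps the needle silhouette at t = %g s; %s", t,
          "move the event or set allow_needle_overlap = TRUE"))
      }
      img <- matrix(im$background, rows, cols)
      img[needle] <- im$needle
      img[bubbles] <- im$bubble
      img <- img + matrix(stats::rnorm(rows * cols, 0, im$noise_sd), rows, cols)
      frames[, , k] <- as.integer(pmin(255, pmax(0, round(img))))
      truth$area_mm2[k] <- area
      truth$tip_y_mm[k] <- tip["y"]; truth$tip_z_mm[k] <- tip["z"]
      truth$tip_row[k] <- -tip["z"] / pitch + 0.5
      truth$tip_col[k] <- tip["y"] / pitch + 0.5
    }
  })

  video <- video_sequence(frames, frame_rate = scene$frame_rate,
                          pixel_pitch_um = scene$pixel_pitch_um,
                          time_offset = scene$time_offset)
  list(video = video, truth = truth)
}

#' Describe a synthetic hydrophone trace
#'
#' The trace superposes (i) a Gaussian noise floor, (ii) band-limited
#' broadband noise bursts with prescribed per-burst RMS, emulating the
#' impulsive metal-to-metal collisions and the cavitation onset, and (iii)
#' exponentially decaying ringing tones in the 10-30 kHz band, emulating
#' the needle's structural eigenfrequencies that persist after the bubbles
#' vanish.
#'
#' @param burst_times trigger-aligned burst centre times, s. The side-cut
#'   firing signature has three bursts (0.015, 0.020, 0.025 s), the
#'   front-cut two (0.020, 0.025 s).
#' @param burst_rms per-burst RMS pressure in Pa (recycled).
#' @param burst_bandwidth upper band edge of the burst noise, Hz.
#' @param burst_duration envelope length of each burst, s.
#' @param ringing_tones list of lists with `frequency` (Hz), `decay` (1/s),
#'   `amplitude` (Pa) and optional `onset` (s; defaults to the last burst
#'   time, or 0 with no bursts).
#' @param noise_floor_rms RMS of the background noise floor, Pa.
#' @param fs sampling rate, Hz (100 000 as recorded).
#' @param duration trace length, s.
#' @param trigger_sample 1-based index of the t = 0 sample.
#' @param seed integer seed.
#' @return object of class `synthetic_audio_spec`.
#' @export
synthetic_audio_spec <- function(burst_times = c(0.015, 0.020, 0.025),
                                 burst_rms = 10,
                                 burst_bandwidth = 40e3,
                                 burst_duration = 1e-3,
                                 ringing_tones = list(
                                   list(frequency = 15e3, decay = 150,
                                        amplitude = 5)),
                                 noise_floor_rms = 0.05,
                                 fs = 1e5, duration = 0.06,
                                 trigger_sample = 1L, seed = 1L) {
  stopifnot(fs > 0, duration > 0)
  n <- round(duration * fs)
  trigger_sample <- as.integer(trigger_sample)
  if (trigger_sample < 1L || trigger_sample > n) {
    stop("trigger_sample outside the trace")
  }
  for (tone in ringing_tones) {
    if (tone$frequency >= fs / 2) {
      stop(sprintf("tone frequency %g Hz is not below the Nyquist rate %g Hz",
                   tone$frequency, fs / 2))
    }
  }
  if (burst_bandwidth >= fs / 2) stop("burst bandwidth must be below fs/2")
  structure(list(burst_times = burst_times,
                 burst_rms = rep_len(burst_rms, length(burst_times)),
                 burst_bandwidth = burst_bandwidth,
                 burst_duration = burst_duration,
                 ringing_tones = ringing_tones,
                 noise_floor_rms = noise_floor_rms,
                 fs = fs, duration = duration, n = n,
                 trigger_sample = trigger_sample, seed = as.integer(seed)),
            class = "synthetic_audio_spec")
}

#' Generate a synthetic hydrophone trace
#'
#' @param spec a [synthetic_audio_spec()].
#' @return an [audio_trace()] (pressure in Pa). Identical spec and seed give
#'   bit-identical samples.
#' @export
generate_audio <- function(spec) {
  stopifnot(inherits(spec, "synthetic_audio_spec"))
  n <- spec$n
  t <- (seq_len(n) - spec$trigger_sample) / spec$fs
  x <- with_local_seed(spec$seed, {
    x <- if (spec$noise_floor_rms > 0) {
      stats::rnorm(n, 0, spec$noise_floor_rms)
    } else numeric(n)
    Lb <- round(spec$burst_duration * spec$fs)
    if (Lb >= 8 && length(spec$burst_times)) {
      bf <- signal::butter(4, spec$burst_bandwidth / (spec$fs / 2),
                           type = "low")
      env <- 0.5 * (1 - cos(2 * pi * seq_len(Lb) / (Lb + 1)))   # Hann bump
      for (i in seq_along(spec$burst_times)) {
        i0 <- which.min(abs(t - spec$burst_times[i])) - Lb %/% 2
        idx <- seq(i0, length.out = Lb)
        keep <- idx >= 1 & idx <= n
        if (!any(keep)) next
        seg <- signal::filtfilt(bf, stats::rnorm(Lb)) * env
        seg <- seg * spec$burst_rms[i] / sqrt(mean(seg^2))
        x[idx[keep]] <- x[idx[keep]] + seg[keep]
      }
    }
    x
  })
  for (tone in spec$ringing_tones) {
    onset <- tone$onset
    if (is.null(onset)) {
      onset <- if (length(spec$burst_times)) max(spec$burst_times) else 0
    }
    dt <- t - onset
    live <- dt >= 0
    x[live] <- x[live] + tone$amplitude * exp(-tone$decay * dt[live]) *
      sin(2 * pi * tone$frequency * dt[live])
  }
  audio_trace(x, fs = spec$fs, trigger_sample = spec$trigger_sample)
}

#' Write a synthetic fixture bundle (TIFF + WAV + ground truth)
#'
#' Generates the scene and audio spec, writes `video.tiff` (8-bit
#' multi-page), `audio.wav` (32-bit float Pa) and `ground_truth.json`
#' (true per-frame areas and tip trajectory, burst times, tone parameters,
#' trigger indices and seeds), plus a `manifest.json` listing the three
#' payload files with MD5 checksums.
#'
#' @param scene a [synthetic_scene()].
#' @param spec a [synthetic_audio_spec()].
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly (list with `files`, `md5`, `seeds`).
#' @export
write_fixture_bundle <- function(scene, spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_video(scene)
  audio <- generate_audio(spec)
  paths <- file.path(out_dir, c("video.tiff", "audio.wav",
                                "ground_truth.json"))
  write_video_tiff(gen$video, paths[1])
  write_audio_wav(audio, paths[2])
  tones <- lapply(spec$ringing_tones, function(x) {
    x[c("frequency", "decay", "amplitude")]
  })
  gt <- list(
    truth = gen$truth,
    burst_times = spec$burst_times,
    ringing_tones = tones,
    video = list(frame_rate = scene$frame_rate,
                 pixel_pitch_um = scene$pixel_pitch_um,
                 time_offset = scene$time_offset,
                 frame_size = scene$frame_size,
                 needle_geometry = scene$needle_geometry,
                 seed = scene$seed),
    audio = list(fs = spec$fs, trigger_sample = spec$trigger_sample,
                 seed = spec$seed))
  jsonlite::write_json(gt, paths[3], auto_unbox = TRUE, digits = 10,
                       dataframe = "columns")
  manifest <- list(files = basename(paths),
                   md5 = unname(tools::md5sum(paths)),
                   seeds = list(video = scene$seed, audio = spec$seed))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

# time-varying bubble radius: growth and collapse over the lifetime, never
# fully degenerate while alive
pulse_radius <- function(r_max, birth, death) {
  function(t) {
    s <- pmin(pmax((t - birth) / (death - birth), 0), 1)
    r_max * (0.15 + 0.85 * sqrt(sin(pi * s)))
  }
}

#' Demonstration scenes emulating the two needle designs fired in water
#'
#' Study-condition scenes: a 14 G needle fired with an abrupt far-end stop
#' at t = 0.025 s, followed by a decaying lateral flexural oscillation and
#' a cluster of transient bubbles in the wake of the tip. The side-cut
#' scene carries a strong lateral oscillation (peak tip velocity about
#' 7.5 m/s) and a bubble cluster living about 0.84 ms; the front-cut scene
#' has negligible lateral motion (sub-mm) with a smaller, shorter-lived
#' cluster (about 0.25 ms). Frames cover t = 0.022 to 0.0285 s so the
#' needle is at its final rest position, bubble-free, in the closing
#' frames.
#'
#' @param seed integer seed.
#' @param bubbles set `FALSE` for a bubble-free recording (emulating the
#'   dense 1.0 % w/v agarose case, where cavitation is essentially
#'   eliminated).
#' @return a [synthetic_scene()].
#' @export
side_cut_demo_scene <- function(seed = 1L, bubbles = TRUE) {
  ev <- list()
  if (bubbles) {
    mk <- function(y, z, r, t0, t1) {
      bubble_event(y, z, a = pulse_radius(r, t0, t1),
                   birth_time = t0, death_time = t1)
    }
    ev <- list(mk(7.35, -4.0, 0.60, 0.02505, 0.02570),
               mk(8.6, -4.9, 0.55, 0.02515, 0.02589),
               mk(7.35, -5.6, 0.50, 0.02510, 0.02560),
               mk(8.7, -6.2, 0.45, 0.02520, 0.02580))
  }
  synthetic_scene(
    needle_geometry = "side_cut",
    motion_profile = firing_motion_profile(stop_time = 0.025, travel_mm = 3,
                                           travel_duration = 0.004,
                                           lateral_amp_mm = 0.7,
                                           lateral_freq = 2000,
                                           lateral_decay = 0.003),
    bubble_events = ev,
    duration = 0.0065, time_offset = 0.022,
    tip_rest_y = 4.8, tip_rest_z = -1.5, seed = seed)
}

#' @rdname side_cut_demo_scene
#' @export
front_cut_demo_scene <- function(seed = 1L, bubbles = TRUE) {
  ev <- list()
  if (bubbles) {
    mk <- function(y, z, r, t0, t1) {
      bubble_event(y, z, a = pulse_radius(r, t0, t1),
                   birth_time = t0, death_time = t1)
    }
    ev <- list(mk(3.6, -5.3, 0.28, 0.02505, 0.02530),
               mk(6.0, -5.4, 0.25, 0.02510, 0.02530),
               mk(4.8, -6.1, 0.22, 0.02508, 0.02528))
  }
  synthetic_scene(
    needle_geometry = "front_cut",
    motion_profile = firing_motion_profile(stop_time = 0.025, travel_mm = 3,
                                           travel_duration = 0.004,
                                           lateral_amp_mm = 0.05,
                                           lateral_freq = 2000,
                                           lateral_decay = 0.003),
    bubble_events = ev,
    duration = 0.0065, time_offset = 0.022,
    tip_rest_y = 4.8, tip_rest_z = -1.5, seed = seed)
}

#' Demonstration hydrophone specs matching the demo scenes
#'
#' The side-cut firing signature carries three broadband bursts (0.015,
#' 0.020, 0.025 s; the last, the far-end stop, loudest), the front-cut two
#' (0.020, 0.025 s); both are followed by decaying ringing tones in the
#' 10-30 kHz band emulating the needle's structural eigenfrequencies.
#'
#' @param seed integer seed.
#' @return a [synthetic_audio_spec()].
#' @export
side_cut_demo_audio <- function(seed = 1L) {
  synthetic_audio_spec(burst_times = c(0.015, 0.020, 0.025),
                       burst_rms = c(5, 8, 20),
                       ringing_tones = list(
                         list(frequency = 15e3, decay = 150, amplitude = 5)),
                       seed = seed)
}

#' @rdname side_cut_demo_audio
#' @export
front_cut_demo_audio <- function(seed = 1L) {
  synthetic_audio_spec(burst_times = c(0.020, 0.025),
                       burst_rms = c(8, 12),
                       ringing_tones = list(
                         list(frequency = 12e3, decay = 120, amplitude = 2),
                         list(frequency = 28e3, decay = 180, amplitude = 1.5)),
                       seed = seed)
}
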