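# Co-registration of the optical and acoustic streams on the trigger
# time axis, and the end-to-end pipeline producing a combined experiment
# report: area series + summary, tip kinematics + motion events,
# spectrogram summary (peak SPL, bursts, ridges) and the hydrodynamic
# characterization (Ca, Re) at the measured peak lateral velocity.

#' Bundle a co-registered recording
#'
#' @param video a [video_sequence()].
#' @param audio an [audio_trace()].
#' @param needle_type `"side_cut"` or `"front_cut"`.
#' @param medium `"water"`, `"agarose_0.3"`, `"agarose_1.0"` or `"custom"`.
#' @param metadata optional named list carried into the report.
#' @return object of class `experiment_record`.
#' @export
experiment_record <- function(video, audio,
                              needle_type = c("side_cut", "front_cut"),
                              medium = c("water", "agarose_0.3",
                                         "agarose_1.0", "custom"),
                              metadata = list()) {
  stopifnot(inherits(video, "video_sequence"), inherits(audio, "audio_trace"))
  structure(list(video = video, audio = audio,
                 needle_type = match.arg(needle_type),
                 medium = match.arg(medium), metadata = metadata),
            class = "experiment_record")
}

#' Map both streams onto the trigger-defined time axis
#'
#' Frame k (1-based) maps to `time_offset + (k - 1) / frame_rate`; sample
#' j maps to `(j - trigger_sample) / fs`. The trigger instant t = 0 — the
#' needle's far-end stop — coincides exactly across streams.
#'
#' @param video a [video_sequence()].
#' @param audio an [audio_trace()].
#' @return list with `frame_times` and `sample_times` (s, trigger-aligned)
#'   and the two mapping functions `frame_to_time(k)`, `sample_to_time(j)`.
#' @export
coregister <- function(video, audio) {
  stopifnot(inherits(video, "video_sequence"), inherits(audio, "audio_trace"))
  if (is.null(video$time_offset) || is.na(video$time_offset)) {
    stop("video carries no trigger reference (time_offset missing)")
  }
  if (is.null(audio$trigger_sample) || is.na(audio$trigger_sample)) {
    stop("audio carries no trigger reference (trigger_sample missing)")
  }
  list(frame_times = frame_times(video),
       sample_times = sample_times(audio),
       frame_to_time = function(k) video$time_offset + (k - 1) / video$frame_rate,
       sample_to_time = function(j) (j - audio$trigger_sample) / audio$fs)
}

medium_flow_constants <- function(medium) {
  switch(medium,
    water = list(rho = 998, mu = 1e-3, p = 101325, p_v = 2339),
    # agarose gels: kinematic viscosity about 5e-6 m2/s reported for a
    # 0.9 % w/v gel; used for both concentrations as an order of magnitude
    agarose_0.3 = ,
    agarose_1.0 = list(rho = 1000, mu = 5e-3, p = 101325, p_v = 2339),
    custom = list(rho = 998, mu = 1e-3, p = 101325, p_v = 2339))
}

#' Default pipeline configuration
#'
#' @param n_rest_frames frames voted into the needle-at-rest reference.
#' @param rest_from `"last"` (default) or `"first"`: which end of the
#'   recording shows the needle at rest. Recordings of a firing cover the
#'   far-end stop, so the needle is at its final rest position, bubble-free,
#'   in the closing frames; pre-firing frames then yield clamped negative
#'   differences, as intended.
#' @param binarize_method,binarize_level see [binarize_frame()].
#' @param area_threshold duration threshold for [summarize_area()], mm2.
#' @param roi optional feature-seeding region `c(r1, r2, c1, c2)`.
#' @param max_features number of features tracked.
#' @param smoothing displacement smoothing, frames.
#' @param v_threshold velocity threshold for motion events, m/s.
#' @param spectrogram_window,spectrogram_overlap display/calibration STFT
#'   parameters (2560/2500 as published).
#' @param burst_window,burst_overlap short STFT used for burst timing.
#' @param bandwidth_fraction_min,spl_rise_db burst detector thresholds.
#' @param tone_band,min_persistence,ridge_rise_db tone-ridge detector
#'   parameters.
#' @param L characteristic obstacle dimension for Re, m (14 G shaft
#'   diameter).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_rest_frames = 5L,
                            rest_from = c("last", "first"),
                            binarize_method = "otsu", binarize_level = 128,
                            area_threshold = 0,
                            roi = NULL, max_features = 2L, smoothing = 5L,
                            v_threshold = 7,
                            spectrogram_window = 2560L,
                            spectrogram_overlap = 2500L,
                            burst_window = 256L, burst_overlap = 192L,
                            bandwidth_fraction_min = 0.5, spl_rise_db = 12,
                            tone_band = c(10e3, 30e3),
                            min_persistence = 0.02, ridge_rise_db = 8,
                            L = 2.109e-3) {
  rest_from <- match.arg(rest_from)
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = 12,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[needlecav] stage %-12s %.2f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full quantification pipeline on a recording
#'
#' Stages: needle-at-rest reference and projected bubble-area series;
#' feature detection and KLT tip tracking with derived kinematics and
#' motion events; calibrated SPL spectrogram with burst and tone-ridge
#' extraction; cavitation and Reynolds numbers evaluated at the measured
#' peak lateral tip velocity with the medium's fluid constants. All time
#' axes share the trigger t = 0 convention and the result is deterministic
#' given the record and config.
#'
#' @param record an [experiment_record()].
#' @param config a [pipeline_config()].
#' @return object of class `needlecav_report`.
#' @export
run_pipeline <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "experiment_record"))
  video <- record$video; audio <- record$audio
  coregister(video, audio)  # validates the trigger references

  ref <- run_stage("rest_ref", {
    n <- min(config$n_rest_frames, n_frames(video))
    ks <- if (config$rest_from == "last") {
      seq(n_frames(video) - n + 1L, n_frames(video))
    } else seq_len(n)
    build_rest_reference(lapply(ks, function(k) video$frames[, , k]),
                         method = config$binarize_method,
                         level = config$binarize_level)
  })
  areas <- run_stage("areas", bubble_area_series(video, ref))
  area_summary <- summarize_area(areas, config$area_threshold)

  kin <- run_stage("tracking", {
    seeds <- detect_features(video$frames[, , 1] * 1.0, roi = config$roi,
                             max_features = config$max_features)
    if (!nrow(seeds)) stop("no trackable features found in the first frame")
    traj <- track_klt(video, seeds)
    kinematics(traj, feature = 1L, smoothing = config$smoothing)
  })
  events <- detect_motion_events(kin, config$v_threshold)

  acoustic <- run_stage("acoustics", {
    spec <- spl_spectrogram(audio, config$spectrogram_window,
                            config$spectrogram_overlap)
    burst_spec <- spl_spectrogram(audio, config$burst_window,
                                  config$burst_overlap)
    list(peak_spl = max(spec$spl),
         peak_spl_frequency = spec$freq_bins[
           arrayInd(which.max(spec$spl), dim(spec$spl))[1]],
         bursts = detect_bursts(burst_spec, config$bandwidth_fraction_min,
                                config$spl_rise_db),
         ridges = detect_tone_ridges(spec, config$tone_band,
                                     config$min_persistence,
                                     config$ridge_rise_db))
  })

  u_peak <- max(abs(kin$vy))
  hydro <- run_stage("hydro", {
    fc <- medium_flow_constants(record$medium)
    if (u_peak > 0) {
      fp <- flow_parameters(u = u_peak, L = config$L, p = fc$p, p_v = fc$p_v,
                            rho = fc$rho, mu = fc$mu)
      Re <- reynolds_number(fp)
      list(u_peak_lateral = u_peak, Ca = cavitation_number(fp), Re = Re,
           regime = as.character(flow_regime(Re)))
    } else {
      list(u_peak_lateral = 0, Ca = NA_real_, Re = 0, regime = "laminar")
    }
  })

  structure(list(
    needle_type = record$needle_type, medium = record$medium,
    areas = areas, area_summary = area_summary,
    kinematics = kin, motion_events = events,
    acoustics = acoustic, hydro = hydro,
    provenance = list(config = unclass(config),
                      config_hash = config_hash(config),
                      metadata = record$metadata,
                      package_version = as.character(
                        utils::packageVersion("needlecav")))),
    class = "needlecav_report")
}

#' @export
print.needlecav_report <- function(x, ...) {
  cat(sprintf("needlecav report: %s needle in %s\n", x$needle_type, x$medium))
  cat(sprintf("  max area       %.4g mm2 at t = %.4g s (duration %.3g ms)\n",
              x$area_summary$max_area, x$area_summary$time_of_max,
              x$area_summary$duration * 1e3))
  cat(sprintf("  peak |vy|      %.3g m/s (stop at t = %.4g s)\n",
              x$hydro$u_peak_lateral, x$motion_events$stop_time))
  cat(sprintf("  peak SPL       %.1f dB re 1 uPa at %.3g kHz\n",
              x$acoustics$peak_spl, x$acoustics$peak_spl_frequency / 1e3))
  cat(sprintf("  bursts         %d; tone ridges: %d\n",
              nrow(x$acoustics$bursts), nrow(x$acoustics$ridges)))
  cat(sprintf("  Ca = %.4g, Re = %.5g (%s)\n",
              x$hydro$Ca, x$hydro$Re, x$hydro$regime))
  invisible(x)
}

report_summary_list <- function(report) {
  list(
    needle_type = report$needle_type,
    medium = report$medium,
    area = list(max_area_mm2 = report$area_summary$max_area,
                time_of_max_s = report$area_summary$time_of_max,
                duration_s = report$area_summary$duration,
                area_threshold_mm2 = report$area_summary$area_threshold,
                n_clamped_frames = report$areas$n_clamped),
    kinematics = list(peak_lateral_velocity_m_s = report$hydro$u_peak_lateral,
                      peak_acceleration_m_s2 = max(
                        sqrt(report$kinematics$ay^2 + report$kinematics$az^2)),
                      stop_time_s = report$motion_events$stop_time,
                      smoothing = report$kinematics$smoothing,
                      n_threshold_crossings = nrow(
                        report$motion_events$crossings)),
    acoustics = list(peak_spl_db_re_1uPa = report$acoustics$peak_spl,
                     peak_spl_frequency_hz = report$acoustics$peak_spl_frequency,
                     n_bursts = nrow(report$acoustics$bursts),
                     burst_times_s = report$acoustics$bursts$time,
                     n_tone_ridges = nrow(report$acoustics$ridges),
                     ridge_frequencies_hz = report$acoustics$ridges$frequency),
    hydro = list(Ca = report$hydro$Ca, Re = report$hydro$Re,
                 regime = report$hydro$regime),
    provenance = report$provenance)
}

#' Write a report to disk (flat CSV series + one JSON summary)
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "needlecav_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(data.frame(time_s = report$areas$times,
                area_mm2 = report$areas$areas), "area_series.csv")
  k <- report$kinematics
  wr(data.frame(time_s = k$times, y_mm = k$y_mm, z_mm = k$z_mm,
                vy_m_s = k$vy, vz_m_s = k$vz,
                ay_m_s2 = k$ay, az_m_s2 = k$az), "kinematics.csv")
  wr(report$acoustics$bursts, "bursts.csv")
  wr(report$acoustics$ridges, "tone_ridges.csv")
  wr(report$motion_events$crossings, "velocity_crossings.csv")
  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(report_summary_list(report), sp, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  paths <- c(paths, sp)
  invisible(paths)
}
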