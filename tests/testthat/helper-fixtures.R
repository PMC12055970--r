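# Shared fixtures. Everything is generated in code; the demo pipelines are
# memoised because several test files exercise the same recordings.

quiet_pipeline <- function(record, config = pipeline_config()) {
  suppressMessages(run_pipeline(record, config))
}

# small static-needle scene for estimator tests
tiny_scene <- function(bubble_events = list(), duration = 10 / 1e5,
                       noise_sd = 5, seed = 7, ...) {
  synthetic_scene(
    motion_profile = list(y = function(t) 0 * t, z = function(t) 0 * t),
    bubble_events = bubble_events,
    duration = duration, frame_size = c(96L, 128L),
    intensity_model = list(background = 220, needle = 30, bubble = 30,
                           noise_sd = noise_sd),
    tip_rest_y = 1.0, tip_rest_z = -0.6, half_width_mm = 0.35,
    taper_mm = 0.4, seed = seed, ...)
}

# hand-built trajectory object for kinematics tests (sub-pixel positions
# free of rasterization)
make_traj <- function(rows, cols, frame_rate = 1e5, pixel_pitch_um = 25) {
  n <- length(rows)
  structure(list(
    times = (seq_len(n) - 1) / frame_rate,
    tracks = list(list(feature_id = 1L, row = rows, col = cols,
                       valid = rep(TRUE, n))),
    pixel_pitch_um = pixel_pitch_um, frame_rate = frame_rate,
    config = list()), class = "klt_trajectories")
}

# translating dark square on a bright background
square_video <- function(n_frames, shift_per_frame = c(0, 2), size = 16L,
                         start = c(20, 20), dims = c(64L, 96L),
                         noise_sd = 0, seed = 1) {
  set.seed(seed)
  frames <- array(0L, dim = c(dims, n_frames))
  for (k in seq_len(n_frames)) {
    img <- matrix(220, dims[1], dims[2])
    r0 <- round(start[1] + shift_per_frame[1] * (k - 1))
    c0 <- round(start[2] + shift_per_frame[2] * (k - 1))
    img[r0:(r0 + size - 1), c0:(c0 + size - 1)] <- 30
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    frames[, , k] <- as.integer(pmin(255, pmax(0, round(img))))
  }
  video_sequence(frames, frame_rate = 1e5, pixel_pitch_um = 25)
}

# sub-pixel translating blob (smooth Gaussian spot) for fractional-shift
# tracking tests; returns video plus the true per-frame positions
blob_video <- function(n_frames, drow, dcol, dims = c(64L, 96L),
                       start = c(30, 30), sigma = 3) {
  frames <- array(0L, dim = c(dims, n_frames))
  rows <- start[1] + drow * (seq_len(n_frames) - 1)
  cols <- start[2] + dcol * (seq_len(n_frames) - 1)
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  for (k in seq_len(n_frames)) {
    img <- 220 - 190 * exp(-((rr - rows[k])^2 + (cc - cols[k])^2) /
                             (2 * sigma^2))
    frames[, , k] <- as.integer(round(img))
  }
  list(video = video_sequence(frames, frame_rate = 1e5, pixel_pitch_um = 25),
       rows = rows, cols = cols)
}

# exhaustive integer-shift SSD search around a patch: brute-force oracle
ssd_shift <- function(I, J, p, w = 7L, max_shift = 5L) {
  rr <- (p[1] - w):(p[1] + w); cc <- (p[2] - w):(p[2] + w)
  tpl <- I[rr, cc]
  best <- c(0, 0); best_ssd <- Inf
  for (dr in -max_shift:max_shift) for (dc in -max_shift:max_shift) {
    r2 <- rr + dr; c2 <- cc + dc
    if (min(r2) < 1 || max(r2) > nrow(J) || min(c2) < 1 || max(c2) > ncol(J))
      next
    ssd <- sum((tpl - J[r2, c2])^2)
    if (ssd < best_ssd) { best_ssd <- ssd; best <- c(dr, dc) }
  }
  best
}

local({
  cache <- new.env(parent = emptyenv())
  demo_run <<- function(which = c("side", "front", "nobubble"), seed = 11) {
    which <- match.arg(which)
    key <- paste(which, seed, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    gen <- switch(which,
      side = generate_video(side_cut_demo_scene(seed = seed)),
      front = generate_video(front_cut_demo_scene(seed = seed + 1)),
      nobubble = generate_video(side_cut_demo_scene(seed = seed + 2,
                                                    bubbles = FALSE)))
    audio <- switch(which,
      side = generate_audio(side_cut_demo_audio(seed = seed)),
      front = generate_audio(front_cut_demo_audio(seed = seed + 1)),
      nobubble = generate_audio(side_cut_demo_audio(seed = seed + 2)))
    rec <- experiment_record(gen$video, audio,
                             needle_type = if (which == "front") "front_cut"
                                           else "side_cut",
                             medium = if (which == "nobubble") "agarose_1.0"
                                      else "water")
    res <- list(gen = gen, report = quiet_pipeline(rec))
    cache[[key]] <- res
    res
  }
})
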