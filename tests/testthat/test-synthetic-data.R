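test_that("default scene parameters reproduce the recording geometry", {
  sc <- synthetic_scene(duration = 3 / 1e5)
  g <- generate_video(sc)
  expect_identical(dim(g$video$frames), c(288L, 384L, 3L))
  expect_equal(g$video$frame_rate, 1e5)
  expect_equal(g$video$pixel_pitch_um, 25)
})

test_that("ground-truth area is the analytic ellipse area", {
  # no bubbles: identically zero
  g0 <- generate_video(tiny_scene())
  expect_true(all(g0$truth$area_mm2 == 0))

  # one circle a = b = 0.2 mm alive over a known frame window
  ev <- bubble_event(2.4, -1.6, a = 0.2,
                     birth_time = 9.5 / 1e5, death_time = 20.5 / 1e5)
  g <- generate_video(tiny_scene(bubble_events = list(ev), duration = 25 / 1e5))
  live <- g$truth$time >= ev$birth_time & g$truth$time < ev$death_time
  expect_equal(sum(live), 11)
  expect_equal(g$truth$area_mm2[live], rep(pi * 0.04, 11), tolerance = 1e-4)
  expect_true(all(g$truth$area_mm2[!live] == 0))
})

test_that("per-frame truth is conserved over disjoint events", {
  evs <- list(
    bubble_event(2.3, -1.0, a = 0.15, b = 0.1,
                 birth_time = 0, death_time = 5 / 1e5),
    bubble_event(2.6, -1.9, a = 0.2,
                 birth_time = 2 / 1e5, death_time = 8 / 1e5))
  g <- generate_video(tiny_scene(bubble_events = evs))
  expected <- vapply(g$truth$time, function(t) {
    tot <- 0
    for (ev in evs) {
      if (t >= ev$birth_time && t < ev$death_time) {
        b <- if (is.null(ev$b)) ev$a else ev$b
        tot <- tot + pi * ev$a * b
      }
    }
    tot
  }, numeric(1))
  expect_equal(g$truth$area_mm2, expected, tolerance = 1e-3)
})

test_that("generation is bit-identical under a fixed seed", {
  ev <- list(bubble_event(2.4, -1.6, 0.15, birth_time = 0,
                          death_time = 5 / 1e5))
  g1 <- generate_video(tiny_scene(bubble_events = ev, seed = 42))
  g2 <- generate_video(tiny_scene(bubble_events = ev, seed = 42))
  expect_identical(g1$video$frames, g2$video$frames)
  a1 <- generate_audio(synthetic_audio_spec(seed = 3))
  a2 <- generate_audio(synthetic_audio_spec(seed = 3))
  expect_identical(a1$samples, a2$samples)
})

test_that("invalid scenes and audio specs are rejected", {
  out <- bubble_event(50, -1.6, 0.1, birth_time = 0, death_time = 1e-4)
  expect_error(generate_video(tiny_scene(bubble_events = list(out))),
               "event 1")
  expect_error(synthetic_audio_spec(ringing_tones = list(
    list(frequency = 6e4, decay = 0, amplitude = 1))), "Nyquist")
  expect_error(synthetic_audio_spec(trigger_sample = 1e7), "trigger")
  # bubbles brighter than the binarization margin violate shadowgraphy
  expect_error(synthetic_scene(intensity_model = list(
    background = 220, needle = 30, bubble = 210, noise_sd = 5)), "bubble")
})

test_that("dark features sit far below background relative to noise", {
  ev <- list(bubble_event(2.4, -1.6, 0.15, birth_time = 0,
                          death_time = 1e-4))
  sc <- tiny_scene(bubble_events = ev)
  g <- generate_video(sc)
  im <- sc$intensity_model
  margin <- im$background - max(im$needle, im$bubble)
  expect_gt(margin, 5 * im$noise_sd)
  # rendered frame is bimodal around the two levels
  f <- g$video$frames[, , 1]
  expect_lt(sum(f > 100 & f < 150) / length(f), 0.01)
})

test_that("synthetic audio components have the prescribed amplitudes", {
  # silence
  s0 <- generate_audio(synthetic_audio_spec(
    burst_times = numeric(0), ringing_tones = list(), noise_floor_rms = 0,
    duration = 0.01))
  expect_true(all(s0$samples == 0))

  # pure tone: rms = A / sqrt(2) within 0.1 %
  A <- 3.7
  tone <- generate_audio(synthetic_audio_spec(
    burst_times = numeric(0), noise_floor_rms = 0, duration = 0.05,
    ringing_tones = list(list(frequency = 10e3, decay = 0, amplitude = A,
                              onset = 0))))
  expect_equal(sqrt(mean(tone$samples^2)), A / sqrt(2), tolerance = 1e-3)

  # bursts carry the requested RMS at the requested times
  spec <- synthetic_audio_spec(burst_times = c(0.015, 0.020, 0.025),
                               burst_rms = 8, noise_floor_rms = 0,
                               ringing_tones = list(), seed = 9)
  au <- generate_audio(spec)
  tt <- sample_times(au)
  for (bt in spec$burst_times) {
    seg <- au$samples[abs(tt - bt) <= 5e-4]
    expect_equal(sqrt(mean(seg^2)), 8, tolerance = 0.15)
  }
  expect_equal(sum(au$samples[abs(tt - 0.0175) < 1e-3]^2), 0)
})

test_that("fixture bundles round-trip through TIFF/WAV/JSON", {
  ev <- list(bubble_event(2.4, -1.6, 0.2, birth_time = 4.5 / 1e5,
                          death_time = 9.5 / 1e5))
  sc <- tiny_scene(bubble_events = ev)
  spec <- synthetic_audio_spec(duration = 0.03, seed = 5)
  out <- withr::local_tempdir()
  manifest <- write_fixture_bundle(sc, spec, out)

  expect_length(manifest$files, 3)
  expect_setequal(manifest$files,
                  c("video.tiff", "audio.wav", "ground_truth.json"))
  expect_true(all(file.exists(file.path(out, manifest$files))))

  g <- generate_video(sc)
  v2 <- read_video_tiff(file.path(out, "video.tiff"))
  expect_identical(v2$frames, g$video$frames)

  au <- generate_audio(spec)
  a2 <- read_audio_wav(file.path(out, "audio.wav"))
  expect_equal(a2$samples, au$samples, tolerance = 1e-5)
  expect_equal(a2$fs, au$fs)

  gt <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                            simplifyVector = TRUE)
  live <- which(gt$truth$area_mm2 > 0)
  expect_equal(gt$truth$area_mm2[live], rep(pi * 0.04, length(live)),
               tolerance = 1e-4)
  expect_equal(gt$burst_times, spec$burst_times)
})
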