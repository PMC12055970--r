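bimodal_frame <- function(dark_px = 500, dims = c(60L, 80L), seed = 1) {
  set.seed(seed)
  f <- matrix(220, dims[1], dims[2])
  f[seq_len(dark_px)] <- 30
  f
}

test_that("binarization separates dark features from background", {
  f <- bimodal_frame(500)
  b <- binarize_frame(f)
  expect_gt(attr(b, "threshold"), 30)
  expect_lt(attr(b, "threshold"), 220)
  expect_equal(sum(b), 500)

  expect_equal(sum(binarize_frame(matrix(220, 10, 10), "fixed", 128)), 0)
  expect_error(binarize_frame(matrix(128, 10, 10)), "fixed")
})

test_that("rest reference majority vote removes noise", {
  clean <- bimodal_frame(700)
  ref1 <- build_rest_reference(clean)
  expect_identical(ref1$rest_mask, unclass(binarize_frame(clean))[, ])
  expect_equal(ref1$rest_dark_count, 700)

  set.seed(3)
  noisy <- lapply(1:5, function(i) {
    matrix(pmax(0, pmin(255, clean + rnorm(length(clean), 0, 45))),
           nrow(clean))
  })
  refn <- build_rest_reference(noisy, method = "fixed", level = 125)
  expect_identical(refn$rest_mask, clean < 125)
  expect_error(build_rest_reference(list()), "at least one")
})

test_that("rest dark count matches the rendered silhouette", {
  sc <- tiny_scene(noise_sd = 0, duration = 1 / 1e5)
  g <- generate_video(sc)
  f <- g$video$frames[, , 1]
  K <- sum(f < 128)  # noiseless: exactly the silhouette pixels
  ref <- build_rest_reference(f)
  expect_equal(ref$rest_dark_count, K)
})

test_that("pixel-count arithmetic reproduces the printed area scale", {
  # rest needle of K pixels; test frame with K + 5600 extra dark pixels at
  # 25 um/pixel must read 5600 * 0.000625 = 3.5 mm2
  rest <- matrix(220, 288, 384)
  rest[1:100, 1:20] <- 30                      # K = 2000 needle pixels
  test <- rest
  test[101:240, 101:140] <- 30                 # + 140 * 40 = 5600 px
  ref <- build_rest_reference(rest, method = "fixed", level = 128)
  v <- video_sequence(array(as.integer(test), c(288, 384, 1)),
                      pixel_pitch_um = 25)
  as <- bubble_area_series(v, ref)
  expect_equal(as$areas, 3.5)

  # identity with the rest frame gives exactly zero
  v0 <- video_sequence(array(as.integer(rest), c(288, 384, 1)),
                       pixel_pitch_um = 25)
  expect_equal(bubble_area_series(v0, ref)$areas, 0)

  # doubling the pitch quadruples the area for the same pixel count
  v2 <- video_sequence(array(as.integer(test), c(288, 384, 1)),
                       pixel_pitch_um = 50)
  expect_equal(bubble_area_series(v2, ref)$areas, 4 * 3.5)

  expect_error(bubble_area_series(square_video(1), ref), "match")
})

test_that("adding dark pixels never decreases the estimated area", {
  rest <- bimodal_frame(300, dims = c(60L, 80L))
  ref <- build_rest_reference(rest, method = "fixed", level = 128)
  set.seed(11)
  prev <- -1
  f <- rest
  for (i in 1:10) {
    bright <- which(f > 128)
    f[sample(bright, 50)] <- 20
    v <- video_sequence(array(as.integer(f), c(60, 80, 1)))
    a <- bubble_area_series(v, ref)$areas
    expect_gte(a, prev)
    prev <- a
  }
})

test_that("estimator recovers generator truth within rasterization slack", {
  set.seed(1)
  px <- 0.025^2
  for (rep in 1:6) {
    n_ev <- sample(1:2, 1)
    centers <- list(c(2.3, -0.8), c(2.6, -1.9))
    evs <- lapply(seq_len(n_ev), function(i) {
      bubble_event(centers[[i]][1] + runif(1, -0.1, 0.1),
                   centers[[i]][2] + runif(1, -0.1, 0.1),
                   a = runif(1, 0.08, 0.2),
                   birth_time = 0, death_time = 6 / 1e5)
    })
    g <- generate_video(tiny_scene(bubble_events = evs, duration = 6 / 1e5,
                                   seed = rep))
    gn <- generate_video(tiny_scene(duration = 3 / 1e5, seed = rep + 100))
    ref <- build_rest_reference(lapply(1:3, function(k) gn$video$frames[, , k]))
    est <- bubble_area_series(g$video, ref)
    err_px <- abs(est$areas - g$truth$area_mm2) / px
    expect_true(all(err_px <= 2 * n_ev + 1e-9),
                info = sprintf("rep %d: max err %.2f px-areas", rep,
                               max(err_px)))
  }
})

test_that("area summaries report max, argmax and duration", {
  t <- (0:99) / 1e5
  a <- rep(0, 100)
  s0 <- summarize_area(area_series(t, a))
  expect_equal(s0$duration, 0)
  expect_equal(s0$max_area, 0)

  a[10:34] <- 1.5            # 25 frames at 100 kfps = 0.25 ms
  s1 <- summarize_area(area_series(t, a))
  expect_equal(s1$duration, 0.25e-3)
  expect_equal(s1$max_area, 1.5)
  expect_equal(s1$time_of_max, t[10])

  a2 <- rep(0, 100); a2[10:93] <- 0.4   # 84 frames = 0.84 ms
  expect_equal(summarize_area(area_series(t, a2))$duration, 0.84e-3)
})

test_that("replicate aggregation computes pointwise mean and sample SD", {
  t <- (0:9) / 1e5
  mk <- function(v) area_series(t, rep(v, 10))
  nine <- replicate_ensemble(rep(list(mk(1.2)), 9),
                             device_ids = rep(1:3, each = 3),
                             replicate_ids = rep(1:3, 3))
  agg9 <- aggregate_replicates(nine)
  expect_equal(agg9$mean_area, rep(1.2, 10))
  expect_equal(agg9$sd_area, rep(0, 10))
  expect_length(nine$series, 9)

  two <- replicate_ensemble(list(mk(0), mk(2)))
  agg2 <- aggregate_replicates(two)
  expect_equal(agg2$mean_area, rep(1, 10))
  expect_equal(agg2$sd_area, rep(sqrt(2), 10))

  off <- area_series(t + 1e-5, rep(1, 10))
  expect_error(replicate_ensemble(list(mk(1), off)), "common time grid")
  expect_error(aggregate_replicates(replicate_ensemble(list(mk(1)))),
               "two")
})

test_that("bubble distance from the needle is measured in mm", {
  rest <- matrix(220, 100, 100)
  rest[, 10] <- 30                       # needle: one column
  ref <- build_rest_reference(rest, method = "fixed", level = 128)
  f <- rest
  f[50, 36] <- 30                        # 26 px right of the needle
  expect_equal(max_bubble_distance(f, ref, pixel_pitch_um = 25), 0.65)
  expect_equal(max_bubble_distance(rest, ref), 0)
})
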