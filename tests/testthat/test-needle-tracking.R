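test_that("minimum-eigenvalue detection finds square corners", {
  v <- square_video(1)
  fts <- detect_features(v$frames[, , 1] * 1.0, max_features = 4)
  expect_equal(nrow(fts), 4)
  corners <- rbind(c(20, 20), c(20, 35), c(35, 20), c(35, 35))
  for (i in 1:4) {
    d <- sqrt((fts$row - corners[i, 1])^2 + (fts$col - corners[i, 2])^2)
    expect_lt(min(d), 4)
  }
  # deterministic ordering: score descending
  expect_true(all(diff(fts$score) <= 0))
})

test_that("a textureless region yields no features, not an error", {
  expect_equal(nrow(detect_features(matrix(128, 50, 50))), 0)
})

test_that("the needle tip vertex ranks among the strongest features", {
  sc <- tiny_scene(noise_sd = 0, duration = 1 / 1e5)
  g <- generate_video(sc)
  fts <- detect_features(g$video$frames[, , 1] * 1.0, max_features = 5)
  tip <- c(g$truth$tip_row[1], g$truth$tip_col[1])
  d <- sqrt((fts$row - tip[1])^2 + (fts$col - tip[2])^2)
  expect_lt(min(d), 5)
})

test_that("KLT holds still on a static scene and follows translation", {
  v1 <- square_video(1)
  vstat <- video_sequence(v1$frames[, , rep(1, 6)], frame_rate = 1e5)
  fts <- detect_features(v1$frames[, , 1] * 1.0, max_features = 2)
  tr <- track_klt(vstat, fts)
  for (t in tr$tracks) {
    expect_true(all(t$valid))
    expect_lt(max(abs(t$col - t$col[1])), 0.1)
    expect_lt(max(abs(t$row - t$row[1])), 0.1)
  }

  vmov <- square_video(10, shift_per_frame = c(0, 2))
  tr2 <- track_klt(vmov, fts)
  steps <- diff(tr2$tracks[[1]]$col)
  expect_true(all(tr2$tracks[[1]]$valid))
  expect_equal(steps, rep(2, 9), tolerance = 0.05)
  expect_lt(max(abs(diff(tr2$tracks[[1]]$row))), 0.1)
})

test_that("tracking stays sub-pixel accurate under noise", {
  # noiseless rigid translation: <= 0.1 px/frame error
  b <- blob_video(8, drow = 0.6, dcol = -1.3)
  seeds <- data.frame(row = 30, col = 30, score = 1)
  tr <- track_klt(b$video, seeds)
  expect_lt(max(abs(tr$tracks[[1]]$row - b$rows)), 0.1)
  expect_lt(max(abs(tr$tracks[[1]]$col - b$cols)), 0.1)

  # noise SD 5 on the 0-255 scale: <= 0.5 px/frame
  set.seed(4)
  vn <- b$video
  vn$frames <- vn$frames +
    array(as.integer(round(rnorm(length(vn$frames), 0, 5))), dim(vn$frames))
  trn <- track_klt(vn, seeds)
  expect_lt(max(abs(diff(trn$tracks[[1]]$row) - 0.6)), 0.5)
  expect_lt(max(abs(diff(trn$tracks[[1]]$col) + 1.3)), 0.5)
})

test_that("KLT agrees with an exhaustive integer-shift SSD oracle", {
  set.seed(8)
  # half-integer shifts are excluded: there the integer oracle itself is a
  # coin flip between the two neighbouring shifts
  shifts <- setdiff(seq(-2, 2, by = 0.25), seq(-1.5, 1.5, by = 1))
  for (i in 1:3) {
    dr <- sample(shifts, 1)
    dc <- sample(shifts, 1)
    b <- blob_video(5, drow = dr, dcol = dc)
    seeds <- data.frame(row = 30, col = 30, score = 1)
    tr <- track_klt(b$video, seeds)$tracks[[1]]
    for (k in 1:4) {
      shift <- ssd_shift(b$video$frames[, , k] * 1.0,
                         b$video$frames[, , k + 1] * 1.0,
                         round(c(tr$row[k], tr$col[k])))
      expect_lt(abs((tr$row[k + 1] - tr$row[k]) - shift[1]), 0.5)
      expect_lt(abs((tr$col[k + 1] - tr$col[k]) - shift[2]), 0.5)
    }
  }
})

test_that("kinematics recovers prescribed derivatives", {
  n <- 60
  # constant position: zero velocity and acceleration
  kc <- kinematics(make_traj(rep(20, n), rep(30, n)), smoothing = 5)
  expect_equal(kc$vy, rep(0, n))
  expect_equal(kc$az, rep(0, n))

  # 1 px (25 um) per frame laterally at 100 kfps = 2.5 m/s
  kl <- kinematics(make_traj(rep(20, n), 30 + seq_len(n) - 1), smoothing = 5)
  expect_equal(kl$vy, rep(2.5, n), tolerance = 0.01)
  expect_true(all(abs(kl$vz) < 1e-9))

  # quadratic fall z = -1/2 a t^2 with a = 8 m/s^2 (downward = -z)
  tt <- (seq_len(n) - 1) / 1e5
  rows <- 20 + 0.5 * 8 * tt^2 * 1e3 / 0.025   # m -> mm -> px
  kq <- kinematics(make_traj(rows, rep(30, n)), smoothing = 5)
  interior <- 5:(n - 5)
  expect_equal(kq$az[interior], rep(-8, length(interior)), tolerance = 0.1)

  expect_error(kinematics(make_traj(rep(1, 2), rep(1, 2))), "stencil")
})

test_that("integrating reported velocity recovers displacement within 1%", {
  n <- 200
  tt <- (seq_len(n) - 1) / 1e5
  y_mm <- 0.4 * sin(2 * pi * 1500 * tt)
  cols <- 40 + y_mm / 0.025
  k <- kinematics(make_traj(rep(20, n), cols), smoothing = 1)
  dt <- 1 / 1e5
  integ <- cumsum((k$vy[-1] + k$vy[-n]) / 2) * dt * 1000   # m/s -> mm
  expect_lt(max(abs(integ - (y_mm[-1] - y_mm[1]))), 0.01 * max(abs(y_mm)))
})

test_that("motion events report crossings and the stop", {
  n <- 101
  tt <- (seq_len(n) - 1) / 1e5
  # velocity ramp 0 -> 10 m/s: quadratic displacement, one upward crossing
  vmax <- 10
  disp_mm <- 0.5 * vmax / max(tt) * tt^2 * 1e3
  kr <- kinematics(make_traj(rep(20, n), 40 + disp_mm / 0.025),
                   smoothing = 1)
  ev <- detect_motion_events(kr, v_threshold = 7)
  expect_equal(sum(ev$crossings$direction == "up" &
                     ev$crossings$axis == "y"), 1)

  # everything below 5.5 m/s: no crossings at that threshold
  slow <- kinematics(make_traj(rep(20, n), 40 + 100 * tt / 0.025 * 1e3 * 0),
                     smoothing = 1)
  expect_equal(nrow(detect_motion_events(slow, 5.5)$crossings), 0)

  # smoothstep stroke: peak speed mid-stroke, stop at the programmed end
  stop_frame <- 80L
  s <- pmin(tt / tt[stop_frame], 1)
  disp <- 2 * (3 * s^2 - 2 * s^3)    # mm, settles at frame 80
  ks <- kinematics(make_traj(rep(20, n), 40 + disp / 0.025), smoothing = 1)
  evs <- detect_motion_events(ks, v_threshold = 7)
  expect_lt(abs(evs$stop_time - tt[stop_frame]), 3 / 1e5 + 1e-12)
})

test_that("trajectories are deterministic", {
  vmov <- square_video(6, shift_per_frame = c(1, 1))
  fts <- detect_features(vmov$frames[, , 1] * 1.0, max_features = 2)
  t1 <- track_klt(vmov, fts)
  t2 <- track_klt(vmov, fts)
  expect_identical(t1$tracks, t2$tracks)
})
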