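# Needle-tip kinematics: minimum-eigenvalue (Shi-Tomasi) corner detection
# seeds a pyramidal Kanade-Lucas-Tomasi tracker; displacement is converted
# to mm via the pixel pitch and differentiated once for velocity, twice for
# acceleration. All positions are sub-pixel (row, col), 1-based.

box_sum <- function(m, w) {
  # sum over a (2w+1)^2 box via an integral image, zero-padded borders
  nr <- nrow(m); nc <- ncol(m)
  ii <- matrix(0, nr + 1, nc + 1)
  ii[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - w, 1); r2 <- pmin(seq_len(nr) + w, nr)
  c1 <- pmax(seq_len(nc) - w, 1); c2 <- pmin(seq_len(nc) + w, nc)
  ii[r2 + 1, c2 + 1] - ii[r1, c2 + 1] - ii[r2 + 1, c1] + ii[r1, c1]
}

image_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  list(gr = gr, gc = gc)
}

#' Detect minimum-eigenvalue (Shi-Tomasi) corner features
#'
#' Scores each pixel by the smaller eigenvalue of the local gradient
#' structure tensor summed over a square window, keeps local maxima above
#' a quality fraction of the strongest score, and returns them in a
#' deterministic order (score descending, then row, then column).
#'
#' @param frame grayscale matrix.
#' @param roi optional region of interest `c(row_min, row_max, col_min,
#'   col_max)`; features are only returned inside it.
#' @param max_features maximum number of features returned.
#' @param window half-width of the structure-tensor window, px.
#' @param min_quality keep features scoring at least this fraction of the
#'   best score.
#' @return data frame with `row`, `col`, `score` (possibly 0 rows for a
#'   textureless region — not an error).
#' @export
detect_features <- function(frame, roi = NULL, max_features = 10L,
                            window = 3L, min_quality = 0.05) {
  stopifnot(is.matrix(frame))
  nr <- nrow(frame); nc <- ncol(frame)
  if (is.null(roi)) roi <- c(1L, nr, 1L, nc)
  stopifnot(length(roi) == 4L, roi[1] >= 1, roi[2] <= nr,
            roi[3] >= 1, roi[4] <= nc)
  g <- image_gradients(frame)
  Srr <- box_sum(g$gr^2, window)
  Scc <- box_sum(g$gc^2, window)
  Src <- box_sum(g$gr * g$gc, window)
  lam <- (Srr + Scc) / 2 - sqrt(((Srr - Scc) / 2)^2 + Src^2)
  # restrict to roi minus a border margin where gradients are undefined
  m <- window + 2L
  keep <- matrix(FALSE, nr, nc)
  keep[max(roi[1], m):min(roi[2], nr - m + 1L),
       max(roi[3], m):min(roi[4], nc - m + 1L)] <- TRUE
  lam[!keep] <- -Inf
  best <- max(lam)
  if (!is.finite(best) || best <= 0) {
    return(data.frame(row = numeric(0), col = numeric(0), score = numeric(0)))
  }
  # 3x3 non-maximum suppression
  is_max <- lam >= best * min_quality
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    shifted[ok_r, ok_c] <- lam[rs[ok_r], cs[ok_c]]
    is_max <- is_max & (lam >= shifted)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(row = numeric(0), col = numeric(0), score = numeric(0)))
  }
  out <- data.frame(row = as.numeric(idx[, 1]), col = as.numeric(idx[, 2]),
                    score = lam[idx])
  out <- out[order(-out$score, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_features)
}

sample_bilinear <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  nr <- nrow(img); nc <- ncol(img)
  r0 <- pmin(pmax(r0, 1L), nr - 1L); c0 <- pmin(pmax(c0, 1L), nc - 1L)
  i00 <- img[cbind(r0, c0)]; i01 <- img[cbind(r0, c0 + 1L)]
  i10 <- img[cbind(r0 + 1L, c0)]; i11 <- img[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

downsample2 <- function(img) {
  nr <- 2L * (nrow(img) %/% 2L); nc <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(nr), seq_len(nc)]
  (img[seq(1, nr, 2), seq(1, nc, 2)] + img[seq(2, nr, 2), seq(1, nc, 2)] +
     img[seq(1, nr, 2), seq(2, nc, 2)] + img[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

build_pyramid <- function(img, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- img
  for (L in seq_len(levels - 1)) pyr[[L + 1]] <- downsample2(pyr[[L]])
  pyr
}

# Single-level iterative Lucas-Kanade update of displacement d (row, col).
lk_refine <- function(I, J, p, d, w, max_iter, tol) {
  offs <- expand.grid(dr = -w:w, dc = -w:w)
  rI <- p[1] + offs$dr; cI <- p[2] + offs$dc
  nr <- nrow(I); nc <- ncol(I)
  if (min(rI) < 2 || max(rI) > nr - 1 || min(cI) < 2 || max(cI) > nc - 1) {
    return(list(d = d, ok = FALSE, residual = Inf))
  }
  Tpl <- sample_bilinear(I, rI, cI)
  gr <- (sample_bilinear(I, rI + 1, cI) - sample_bilinear(I, rI - 1, cI)) / 2
  gc <- (sample_bilinear(I, rI, cI + 1) - sample_bilinear(I, rI, cI - 1)) / 2
  G <- matrix(c(sum(gr * gr), sum(gr * gc), sum(gr * gc), sum(gc * gc)), 2, 2)
  if (abs(det(G)) < 1e-12) return(list(d = d, ok = FALSE, residual = Inf))
  Ginv <- solve(G)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    rJ <- rI + d[1]; cJ <- cI + d[2]
    if (min(rJ) < 2 || max(rJ) > nrow(J) - 1 ||
        min(cJ) < 2 || max(cJ) > ncol(J) - 1) {
      return(list(d = d, ok = FALSE, residual = Inf))
    }
    err <- Tpl - sample_bilinear(J, rJ, cJ)
    resid <- sqrt(mean(err^2))
    step <- Ginv %*% c(sum(gr * err), sum(gc * err))
    d <- d + as.numeric(step)
    if (sqrt(sum(step^2)) < tol) break
  }
  list(d = d, ok = TRUE, residual = resid)
}

#' Track features through a video with pyramidal KLT
#'
#' Iterative local least-squares (Lucas-Kanade) displacement estimation,
#' coarse-to-fine over an image pyramid, applied frame to frame. A feature
#' is invalidated — a flagged outcome, not an error — when its patch exits
#' the frame or the final intensity residual exceeds `max_residual`; once
#' lost it stays lost, so valid segments are contiguous from the first
#' frame. The tracker is fully deterministic.
#'
#' @param video a [video_sequence()].
#' @param seeds data frame with `row`, `col` positions in the first frame
#'   (e.g. from [detect_features()]).
#' @param pyramid_levels number of pyramid levels.
#' @param window patch size in px (odd).
#' @param max_iter maximum Lucas-Kanade iterations per level.
#' @param tol convergence tolerance on the update step, px.
#' @param max_residual RMS intensity residual (0-255 scale) above which a
#'   feature is declared lost.
#' @return object of class `klt_trajectories`: list with `times` and
#'   `tracks`, one track per seed holding `row`, `col` (n_frames each,
#'   `NA` when invalid) and `valid`.
#' @export
track_klt <- function(video, seeds, pyramid_levels = 3L, window = 15L,
                      max_iter = 30L, tol = 0.01, max_residual = 25) {
  stopifnot(inherits(video, "video_sequence"), nrow(seeds) >= 1,
            window %% 2 == 1)
  nf <- n_frames(video)
  w <- (window - 1L) %/% 2L
  nfeat <- nrow(seeds)
  tracks <- lapply(seq_len(nfeat), function(i) {
    list(feature_id = i,
         row = c(seeds$row[i], rep(NA_real_, nf - 1L)),
         col = c(seeds$col[i], rep(NA_real_, nf - 1L)),
         valid = c(TRUE, rep(FALSE, nf - 1L)))
  })
  pyrI <- build_pyramid(video$frames[, , 1] * 1.0, pyramid_levels)
  for (k in seq_len(nf - 1L)) {
    pyrJ <- build_pyramid(video$frames[, , k + 1L] * 1.0, pyramid_levels)
    for (i in seq_len(nfeat)) {
      tr <- tracks[[i]]
      if (!tr$valid[k]) next
      p <- c(tr$row[k], tr$col[k])
      d <- c(0, 0)
      ok <- TRUE; resid <- Inf
      for (L in pyramid_levels:1) {
        scale <- 2^(L - 1L)
        pL <- (p - 0.5) / scale + 0.5
        res <- lk_refine(pyrI[[L]], pyrJ[[L]], pL, d / scale, w,
                         max_iter, tol)
        if (!res$ok) {
          # a miss at a coarse level is tolerable; at the finest it is a loss
          if (L == 1L) { ok <- FALSE; break } else next
        }
        d <- res$d * scale
        resid <- res$residual
      }
      if (ok && resid <= max_residual) {
        tracks[[i]]$row[k + 1L] <- p[1] + d[1]
        tracks[[i]]$col[k + 1L] <- p[2] + d[2]
        tracks[[i]]$valid[k + 1L] <- TRUE
      }
    }
    pyrI <- pyrJ
  }
  structure(list(times = frame_times(video), tracks = tracks,
                 pixel_pitch_um = video$pixel_pitch_um,
                 frame_rate = video$frame_rate,
                 config = list(pyramid_levels = pyramid_levels,
                               window = window, max_iter = max_iter,
                               tol = tol, max_residual = max_residual)),
            class = "klt_trajectories")
}

#' @export
print.klt_trajectories <- function(x, ...) {
  nv <- vapply(x$tracks, function(t) sum(t$valid), integer(1))
  cat(sprintf("KLT trajectories: %d features over %d frames (valid: %s)\n",
              length(x$tracks), length(x$times),
              paste(nv, collapse = ", ")))
  invisible(x)
}

# centered moving average; the window shrinks symmetrically near the ends
# so that linear trends pass through unchanged everywhere
ma_partial <- function(x, k) {
  if (k <= 1) return(x)
  h <- k %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    mean(x[(i - hi):(i + hi)])
  }, numeric(1))
}

# first derivative, second-order accurate: central interior, one-sided ends
deriv1 <- function(x, h) {
  n <- length(x)
  if (n < 3) stop("need at least 3 points for differentiation")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * h)
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * h)
  d
}

#' Derive tip kinematics from a tracked trajectory
#'
#' Converts the first contiguous valid segment of a track to physical
#' displacement (y = +columns, z = -rows, in mm, relative to the first
#' tracked frame), optionally smooths the displacement with a centered
#' moving average, then differentiates once for velocity and twice for
#' acceleration (second-order central differences, one-sided second-order
#' stencils at the ends). Displacement uncertainty is about one pixel
#' (25 um at the default optics), which double differencing at 100 kHz
#' amplifies; hence the default 5-frame smoothing.
#'
#' @param traj a [track_klt()] result.
#' @param feature index of the track to use.
#' @param smoothing moving-average length in frames (1 = raw).
#' @return object of class `kinematics_series` with `times`, displacement
#'   `y_mm`/`z_mm`, velocity `vy`/`vz` (m/s), acceleration `ay`/`az`
#'   (m/s2), and a `smoothing` descriptor.
#' @export
kinematics <- function(traj, feature = 1L, smoothing = 5L) {
  stopifnot(inherits(traj, "klt_trajectories"))
  tr <- traj$tracks[[feature]]
  n_valid <- match(FALSE, tr$valid, nomatch = length(tr$valid) + 1L) - 1L
  if (n_valid < 3) stop("track shorter than the 3-point derivative stencil")
  idx <- seq_len(n_valid)
  pitch_mm <- traj$pixel_pitch_um / 1000
  y <- (tr$col[idx] - tr$col[1]) * pitch_mm
  z <- -(tr$row[idx] - tr$row[1]) * pitch_mm
  if (smoothing > 1) {
    y <- ma_partial(y, smoothing)
    z <- ma_partial(z, smoothing)
  }
  h <- 1 / traj$frame_rate
  vy <- deriv1(y, h) / 1000   # mm/s -> m/s
  vz <- deriv1(z, h) / 1000
  ay <- deriv1(vy, h)
  az <- deriv1(vz, h)
  structure(list(times = traj$times[idx], y_mm = y, z_mm = z,
                 vy = vy, vz = vz, ay = ay, az = az,
                 smoothing = if (smoothing > 1) {
                   sprintf("moving_average_%d_frames", smoothing)
                 } else "raw",
                 pixel_pitch_um = traj$pixel_pitch_um),
            class = "kinematics_series")
}

#' @export
print.kinematics_series <- function(x, ...) {
  cat(sprintf("Kinematics: %d frames, smoothing = %s\n",
              length(x$times), x$smoothing))
  cat(sprintf("  peak |vy| %.3g m/s, peak |vz| %.3g m/s, peak |a| %.3g m/s2\n",
              max(abs(x$vy)), max(abs(x$vz)),
              max(sqrt(x$ay^2 + x$az^2))))
  invisible(x)
}

#' @export
plot.kinematics_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  tms <- x$times * 1e3
  graphics::matplot(tms, cbind(x$y_mm, x$z_mm), type = "l", lty = 1,
                    xlab = "", ylab = "displacement (mm)", ...)
  graphics::legend("topleft", c("y", "z"), col = 1:2, lty = 1, bty = "n")
  graphics::matplot(tms, cbind(x$vy, x$vz), type = "l", lty = 1,
                    xlab = "", ylab = "velocity (m/s)")
  graphics::matplot(tms, cbind(x$ay, x$az), type = "l", lty = 1,
                    xlab = "time after trigger (ms)",
                    ylab = expression(paste("acceleration (m/", s^2, ")")))
  invisible(x)
}

#' Detect velocity-threshold crossings and the stop event
#'
#' Lists every time the per-axis velocity magnitude crosses `v_threshold`
#' (in either direction) and estimates the stop time as the moment of
#' maximum deceleration magnitude after peak speed — the abrupt far-end
#' stop of the fired needle.
#'
#' @param kin a [kinematics_series()].
#' @param v_threshold velocity threshold, m/s. Cavitation onset in the
#'   recordings coincides with lateral tip velocities above about 7 m/s;
#'   below 5.5 m/s no activity is observed.
#' @return object of class `motion_events`: `stop_time` (s) and a data
#'   frame `crossings` with `time`, `axis`, `value`, `direction`, sorted
#'   by time.
#' @export
detect_motion_events <- function(kin, v_threshold = 7) {
  stopifnot(inherits(kin, "kinematics_series"))
  crossings <- data.frame(time = numeric(0), axis = character(0),
                          value = numeric(0), direction = character(0))
  for (axis in c("y", "z")) {
    v <- abs(kin[[paste0("v", axis)]])
    above <- v > v_threshold
    chg <- which(diff(above) != 0)
    if (length(chg)) {
      crossings <- rbind(crossings, data.frame(
        time = kin$times[chg + 1L], axis = axis, value = v[chg + 1L],
        direction = ifelse(above[chg + 1L], "up", "down")))
    }
  }
  crossings <- crossings[order(crossings$time), , drop = FALSE]
  rownames(crossings) <- NULL
  speed <- sqrt(kin$vy^2 + kin$vz^2)
  k_pk <- which.max(speed)
  stop_time <- if (k_pk < length(speed)) {
    amag <- sqrt(kin$ay^2 + kin$az^2)
    after <- seq(k_pk, length(speed))
    kin$times[after[which.max(amag[after])]]
  } else kin$times[k_pk]
  structure(list(stop_time = stop_time, crossings = crossings,
                 v_threshold = v_threshold),
            class = "motion_events")
}

#' @export
print.motion_events <- function(x, ...) {
  cat(sprintf("Motion events: stop at t = %.4g s; %d crossings of %g m/s\n",
              x$stop_time, nrow(x$crossings), x$v_threshold))
  invisible(x)
}
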