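# Passive acoustic monitoring: calibrated sound-pressure-level (SPL)
# spectrograms of hydrophone traces, with extraction of broadband bursts
# (impulsive device collisions, cavitation onset) and persistent narrowband
# ridges (structural ringing of the needle at 10-30 kHz).
#
# Underwater reference pressure: 1 uPa. Silence maps to a -20 dB re 1 uPa
# sentinel floor, far below any physical level in these recordings.

P_REF <- 1e-6
SPL_FLOOR_DB <- -20

#' Band sound pressure level of a pressure segment
#'
#' `20 log10(p_rms / 1 uPa)`; an all-zero segment maps to the documented
#' -20 dB floor. An RMS of 1 Pa reads 120 dB; 56.23 Pa reads 155.0 dB.
#'
#' @param segment numeric vector, pressure in Pa.
#' @return SPL in dB re 1 uPa.
#' @export
band_spl <- function(segment) {
  stopifnot(is.numeric(segment), length(segment) >= 1)
  p_rms <- sqrt(mean(segment^2))
  if (p_rms <= 0) return(SPL_FLOOR_DB)
  max(SPL_FLOOR_DB, 20 * log10(p_rms / P_REF))
}

#' Inverse of [band_spl()]: RMS pressure implied by an SPL
#' @param spl_db SPL in dB re 1 uPa.
#' @return RMS pressure in Pa (155 dB corresponds to about 56.23 Pa).
#' @export
spl_to_pressure <- function(spl_db) P_REF * 10^(spl_db / 20)

#' Calibrated SPL spectrogram of a hydrophone trace
#'
#' Short-time Fourier transform with the stated window and overlap
#' (defaults 2560 samples with 2500 of overlap, i.e. 39.06 Hz frequency
#' resolution and 0.6 ms hop at 100 kHz). The default scaling is the
#' amplitude-spectrum ("band SPL") convention with the window's coherent
#' gain compensated, so a pure tone's peak bin reads the tone's true band
#' SPL. A spectral-density convention (dB re 1 uPa^2/Hz) is available via
#' `convention = "density"`; the two differ by 10 log10(ENBW x df).
#' Time bins are window centres, trigger-aligned (the trigger sample maps
#' to t = 0).
#'
#' @param trace an [audio_trace()].
#' @param window_size window length in samples.
#' @param overlap overlap between successive windows in samples.
#' @param window_function `"hann"` or `"rectangular"`.
#' @param convention `"band"` (tone-calibrated, default) or `"density"`.
#' @return object of class `spl_spectrogram` with `time_bins` (s),
#'   `freq_bins` (Hz, 0..fs/2), `spl` (freq x time matrix, dB re 1 uPa)
#'   and the analysis metadata.
#' @export
spl_spectrogram <- function(trace, window_size = 2560L, overlap = 2500L,
                            window_function = c("hann", "rectangular"),
                            convention = c("band", "density")) {
  stopifnot(inherits(trace, "audio_trace"))
  window_function <- match.arg(window_function)
  convention <- match.arg(convention)
  ws <- as.integer(window_size); ov <- as.integer(overlap)
  hop <- ws - ov
  if (hop <= 0) stop("overlap must be smaller than the window size")
  x <- trace$samples
  if (length(x) < ws) {
    stop(sprintf("trace (%d samples) shorter than the window (%d)",
                 length(x), ws))
  }
  w <- if (window_function == "hann") {
    0.5 * (1 - cos(2 * pi * seq_len(ws) / (ws + 1)))
  } else rep(1, ws)
  starts <- seq(1L, length(x) - ws + 1L, by = hop)
  fr <- vapply(starts, function(s) x[s:(s + ws - 1L)] * w, numeric(ws))
  X <- stats::mvfft(fr)
  nb <- ws %/% 2L + 1L
  mag <- Mod(X[seq_len(nb), , drop = FALSE])
  if (convention == "band") {
    # one-sided amplitude spectrum, coherent gain compensated; tone rms in
    # its peak bin is amplitude/sqrt(2)
    amp <- mag * 2 / sum(w)
    amp[1, ] <- mag[1, ] / sum(w)
    if (ws %% 2L == 0L) amp[nb, ] <- mag[nb, ] / sum(w)
    p_rms <- amp / sqrt(2)
    p_rms[1, ] <- amp[1, ]
    if (ws %% 2L == 0L) p_rms[nb, ] <- amp[nb, ]
    spl <- ifelse(p_rms > 0, 20 * log10(p_rms / P_REF), SPL_FLOOR_DB)
  } else {
    psd <- mag^2 * 2 / (trace$fs * sum(w^2))
    psd[1, ] <- psd[1, ] / 2
    if (ws %% 2L == 0L) psd[nb, ] <- psd[nb, ] / 2
    spl <- ifelse(psd > 0, 10 * log10(psd / P_REF^2), SPL_FLOOR_DB)
  }
  spl <- pmax(spl, SPL_FLOOR_DB)
  centers <- starts + (ws - 1) / 2
  structure(list(
    time_bins = (centers - trace$trigger_sample) / trace$fs,
    freq_bins = seq(0L, ws %/% 2L) * trace$fs / ws,
    spl = spl,
    window_size = ws, overlap = ov, hop = hop,
    window_function = window_function, convention = convention,
    fs = trace$fs, floor_db = SPL_FLOOR_DB),
    class = "spl_spectrogram")
}

#' @export
print.spl_spectrogram <- function(x, ...) {
  cat(sprintf(
    "SPL spectrogram: %d freq x %d time bins (df = %.4g Hz, hop = %.4g ms)\n",
    length(x$freq_bins), length(x$time_bins), x$freq_bins[2],
    1e3 * x$hop / x$fs))
  cat(sprintf("  window %d/%d (%s), %s convention, peak %.1f dB re 1 uPa\n",
              x$window_size, x$overlap, x$window_function, x$convention,
              max(x$spl)))
  invisible(x)
}

#' @export
plot.spl_spectrogram <- function(x, ...) {
  graphics::image(x$time_bins * 1e3, x$freq_bins / 1e3, t(x$spl),
                  xlab = "time after trigger (ms)", ylab = "frequency (kHz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Detect broadband bursts in an SPL spectrogram
#'
#' A time bin qualifies when at least `bandwidth_fraction_min` of the
#' frequency bins exceed their per-frequency running median (along time)
#' by `spl_rise_db`; adjacent qualifying bins merge into one event, timed
#' and characterized at the bin of maximum SPL. A narrowband tone never
#' qualifies because it elevates only a small fraction of the bins.
#'
#' Burst timing needs finer temporal resolution than the 2560-sample
#' display window; compute the input spectrogram with a short window
#' (e.g. 256 samples, 192 overlap) when bursts a few ms apart must be
#' resolved.
#'
#' @param spec an [spl_spectrogram()].
#' @param bandwidth_fraction_min minimum fraction of frequency bins
#'   elevated simultaneously (default 0.5).
#' @param spl_rise_db required rise over the running median, dB.
#' @return data frame with one row per burst: `time` (s), `peak_spl`
#'   (dB re 1 uPa), `peak_frequency` (Hz), `bandwidth_fraction`.
#' @export
detect_bursts <- function(spec, bandwidth_fraction_min = 0.5,
                          spl_rise_db = 12) {
  stopifnot(inherits(spec, "spl_spectrogram"))
  nt <- length(spec$time_bins)
  k <- min(nt - (1 - nt %% 2L), 31L)
  empty <- data.frame(time = numeric(0), peak_spl = numeric(0),
                      peak_frequency = numeric(0),
                      bandwidth_fraction = numeric(0))
  if (nt < 3 || k < 3) return(empty)
  bg <- t(apply(spec$spl, 1, stats::runmed, k = k))
  elevated <- spec$spl > bg + spl_rise_db
  frac <- colMeans(elevated)
  qual <- frac >= bandwidth_fraction_min
  if (!any(qual)) return(empty)
  runs <- rle(qual)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- empty
  for (i in which(runs$values)) {
    cols <- starts[i]:ends[i]
    sub <- spec$spl[, cols, drop = FALSE]
    pk <- arrayInd(which.max(sub), dim(sub))
    out <- rbind(out, data.frame(
      time = spec$time_bins[cols[pk[2]]],
      peak_spl = sub[pk],
      peak_frequency = spec$freq_bins[pk[1]],
      bandwidth_fraction = max(frac[cols])))
  }
  out
}

#' Detect persistent narrowband tone ridges
#'
#' Within `band`, a frequency bin belongs to a ridge while its SPL exceeds
#' the band's per-time median (the local broadband background) by
#' `rise_db` for at least `min_persistence` seconds of consecutive time
#' bins. Adjacent ridge bins merge; each ridge reports the frequency of
#' its strongest bin, the onset, the persistence and the mean SPL over the
#' ridge. Such ridges outliving the optical bubble activity identify
#' structural eigenfrequencies of the needle rather than bubble ringing.
#'
#' @param spec an [spl_spectrogram()].
#' @param band frequency range searched, Hz (default the 10-30 kHz band).
#' @param min_persistence minimum ridge duration, s.
#' @param rise_db required excess over the band median, dB.
#' @return data frame with `frequency` (Hz), `onset` (s), `persistence`
#'   (s), `mean_spl` (dB).
#' @export
detect_tone_ridges <- function(spec, band = c(10e3, 30e3),
                               min_persistence = 0.02, rise_db = 8) {
  stopifnot(inherits(spec, "spl_spectrogram"), length(band) == 2L,
            band[1] >= 0, band[2] <= spec$fs / 2)
  sel <- which(spec$freq_bins >= band[1] & spec$freq_bins <= band[2])
  empty <- data.frame(frequency = numeric(0), onset = numeric(0),
                      persistence = numeric(0), mean_spl = numeric(0))
  if (length(sel) < 3) return(empty)
  sub <- spec$spl[sel, , drop = FALSE]
  bg <- apply(sub, 2, stats::median)
  excess <- sweep(sub, 2, bg) > rise_db
  dt <- spec$hop / spec$fs
  min_bins <- max(2L, ceiling(min_persistence / dt))
  # longest qualifying run per bin; a run must also clear the rise
  # threshold by 3 dB on average — successive windows share most of their
  # samples, so a single noise excursion smears over many time bins and
  # bare threshold-grazing runs are not evidence of a tone
  excess_db <- sweep(sub, 2, bg)
  bin_runs <- vapply(seq_len(nrow(sub)), function(b) {
    r <- rle(excess[b, ])
    hits <- which(r$values & r$lengths >= min_bins)
    if (!length(hits)) return(c(NA_integer_, NA_integer_))
    ends <- cumsum(r$lengths)
    for (j in hits[order(-r$lengths[hits])]) {
      run <- (ends[j] - r$lengths[j] + 1L):ends[j]
      if (mean(excess_db[b, run]) >= rise_db + 3) {
        return(c(run[1], run[length(run)]))
      }
    }
    c(NA_integer_, NA_integer_)
  }, integer(2))
  ridge_bins <- which(!is.na(bin_runs[1, ]))
  if (!length(ridge_bins)) return(empty)
  # merge adjacent frequency bins into ridges
  groups <- cumsum(c(1L, diff(ridge_bins) > 1L))
  out <- empty
  for (g in unique(groups)) {
    bins <- ridge_bins[groups == g]
    strength <- vapply(bins, function(b) {
      mean(sub[b, bin_runs[1, b]:bin_runs[2, b]])
    }, numeric(1))
    b <- bins[which.max(strength)]
    run <- bin_runs[, b]
    out <- rbind(out, data.frame(
      frequency = spec$freq_bins[sel[b]],
      onset = spec$time_bins[run[1]],
      persistence = (run[2] - run[1] + 1L) * dt,
      mean_spl = max(strength)))
  }
  out[order(out$frequency), , drop = FALSE]
}
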