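#' Extract normal-to-normal (NN) intervals from a beat series
#'
#' An RR interval enters HRV analysis only when both the beat that starts it
#' and the beat that ends it are labelled `N` (sinus). Each retained interval
#' is timestamped at its terminating beat.
#'
#' @param beats A [beat_series()].
#' @return An object of class `"nn_series"`: list with `time` (s), `rr_ms`,
#'   and `n_beats` (total beats seen). Zero retained intervals gives an empty
#'   series with a warning.
#' @export
extract_nn <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  n <- length(beats$beat_time)
  keep <- if (n >= 2L) {
    which(beats$label[-1L] == "N" & beats$label[-n] == "N") + 1L
  } else integer(0)
  out <- structure(
    list(time = beats$beat_time[keep], rr_ms = beats$rr_ms[keep],
         n_beats = n),
    class = "nn_series"
  )
  if (length(keep) == 0L) warning("no NN intervals in beat series")
  out
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> %d NN intervals from %d beats\n",
              length(x$time), x$n_beats))
  invisible(x)
}

#' Per-epoch heart rate and SDRR
#'
#' HR (bpm) is 60000 divided by the mean NN interval (ms) within the epoch;
#' SDRR is the sample standard deviation (n - 1 denominator) of the NN
#' intervals. Epochs holding fewer than `min_nn_per_epoch` NN intervals get
#' `NA` for both. Intervals are assigned to epochs by their terminating beat
#' time.
#'
#' @param nn An `"nn_series"` from [extract_nn()].
#' @param epochs Epoch table (needs `epoch_index` and `t_start`), e.g. from
#'   [classify_posture()].
#' @param config A [phrv_config()].
#' @return A data.frame with `epoch_index`, `hr_bpm`, `sdrr_ms`, `n_nn`.
#' @export
epoch_hr_sdrr <- function(nn, epochs, config = phrv_config()) {
  idx <- findInterval(nn$time, epochs$t_start + config$epoch_s) + 1L
  inside <- nn$time >= epochs$t_start[1L] &
    idx <= nrow(epochs)
  out <- data.frame(epoch_index = epochs$epoch_index,
                    hr_bpm = NA_real_, sdrr_ms = NA_real_, n_nn = 0L)
  if (any(inside)) {
    sp <- split(nn$rr_ms[inside], idx[inside])
    for (k in names(sp)) {
      i <- as.integer(k)
      rr <- sp[[k]]
      out$n_nn[i] <- length(rr)
      if (length(rr) >= config$min_nn_per_epoch) {
        out$hr_bpm[i] <- 60000 / mean(rr)
        out$sdrr_ms[i] <- stats::sd(rr)
      }
    }
  }
  out
}

#' Resample an NN series to a uniform 2 Hz tachogram
#'
#' Fits a cubic spline through (terminating beat time, NN interval) and
#' evaluates it on a uniform 0.5 s grid. Grid spans bridged across an
#' annotation gap longer than `max_gap_s` are marked invalid; downstream
#' epoch statistics over invalid spans are reported as `NA`.
#'
#' @param nn An `"nn_series"`.
#' @param config A [phrv_config()].
#' @return An object of class `"resampled_rr"`: list with `t` (s), `rr_ms`,
#'   `valid` (logical), `fs` (Hz).
#' @export
resample_2hz <- function(nn, config = phrv_config()) {
  if (length(nn$time) < 4L) {
    stop("need at least 4 NN intervals for cubic-spline resampling",
         call. = FALSE)
  }
  fs <- config$resample_hz
  t0 <- ceiling(nn$time[1L] * fs) / fs
  t1 <- floor(nn$time[length(nn$time)] * fs) / fs
  if (t1 <= t0) stop("NN series too short to resample", call. = FALSE)
  grid <- seq(t0, t1, by = 1 / fs)
  sp <- stats::splinefun(nn$time, nn$rr_ms, method = "fmm")
  rr <- sp(grid)
  valid <- rep(TRUE, length(grid))
  gaps <- which(diff(nn$time) > config$max_gap_s)
  for (gk in gaps) {
    valid[grid > nn$time[gk] & grid < nn$time[gk + 1L]] <- FALSE
  }
  structure(list(t = grid, rr_ms = rr, valid = valid, fs = fs),
            class = "resampled_rr")
}

#' @export
print.resampled_rr <- function(x, ...) {
  cat(sprintf("<resampled_rr> %d samples @ %g Hz, %.1f%% valid\n",
              length(x$t), x$fs, 100 * mean(x$valid)))
  invisible(x)
}

band_edges <- function(band, config) {
  switch(band,
         VLF = config$vlf_band_hz,
         LF  = config$lf_band_hz,
         HF  = config$hf_band_hz,
         stop("band must be one of VLF, LF, HF", call. = FALSE))
}

#' Complex demodulation of one frequency band
#'
#' Multiplies the mean-removed 2 Hz tachogram by `exp(-i 2 pi f0 t)` with
#' `f0` the arithmetic band centre, low-pass filters the product at half the
#' band width (zero-phase), and reads off the band's time-resolved
#' amplitude `2 |y|` (so a sinusoid of peak amplitude A returns A) and
#' instantaneous frequency `f0 + (1 / 2 pi) dphi/dt` from the unwrapped
#' phase (central differences, clamped to the band edges). Where the
#' amplitude is numerically zero the instantaneous frequency is reported as
#' `f0`.
#'
#' @param rs A `"resampled_rr"` from [resample_2hz()].
#' @param band One of `"VLF"`, `"LF"`, `"HF"`.
#' @param config A [phrv_config()].
#' @return An object of class `"band_demod"`: list with `band`, `f0`, `t`,
#'   `amp_ms`, `inst_freq_hz`, `valid`.
#' @export
complex_demodulate <- function(rs, band, config = phrv_config()) {
  stopifnot(inherits(rs, "resampled_rr"))
  edges <- band_edges(band, config)
  f0 <- mean(edges)
  halfbw <- diff(edges) / 2
  trel <- rs$t - rs$t[1L]
  x <- rs$rr_ms - mean(rs$rr_ms)
  rot <- exp(-2i * pi * f0 * trel)
  y <- x * rot
  filt <- signal::butter(4, halfbw / (rs$fs / 2), type = "low")
  y_lp <- complex(
    real = zero_phase(Re(y), filt, rs$fs, halfbw),
    imaginary = zero_phase(Im(y), filt, rs$fs, halfbw)
  )
  amp <- 2 * Mod(y_lp)
  phi <- unwrap_phase(Arg(y_lp))
  n <- length(phi)
  dphi <- numeric(n)
  if (n >= 3L) {
    dphi[2:(n - 1L)] <- (phi[3:n] - phi[1:(n - 2L)]) / (2 / rs$fs)
    dphi[1L] <- dphi[2L]
    dphi[n] <- dphi[n - 1L]
  }
  freq <- f0 + dphi / (2 * pi)
  freq <- pmin(edges[2L], pmax(edges[1L], freq))
  freq[amp < 1e-9] <- f0
  structure(
    list(band = band, f0 = f0, t = rs$t, amp_ms = amp,
         inst_freq_hz = freq, valid = rs$valid),
    class = "band_demod"
  )
}

unwrap_phase <- function(phi) {
  if (length(phi) < 2L) return(phi)
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  phi[1L] + cumsum(c(0, d))
}

#' Per-epoch band amplitudes, HF frequency and LF/HF
#'
#' Averages each band's demodulated amplitude within every 30 s epoch and
#' takes the amplitude-weighted mean of the HF instantaneous frequency.
#' LF/HF follows `lfhf_convention`: `(lf_amp / hf_amp)^2` for `"power"` (the
#' default, matching the customary power-ratio units) or the plain amplitude
#' ratio. Epochs overlapping invalid resampled spans, epochs without
#' demodulated samples, and ratios with a zero HF amplitude are `NA`.
#'
#' @param demods Named list with elements `vlf`, `lf`, `hf`, each a
#'   `"band_demod"` on the same grid.
#' @param epochs Epoch table with `epoch_index`, `t_start`.
#' @param config A [phrv_config()].
#' @return Data.frame with `epoch_index`, `vlf_amp_ms`, `lf_amp_ms`,
#'   `hf_amp_ms`, `hf_freq_hz`, `lf_hf`.
#' @export
epoch_band_stats <- function(demods, epochs, config = phrv_config()) {
  stopifnot(all(c("vlf", "lf", "hf") %in% names(demods)))
  tt <- demods$hf$t
  idx <- findInterval(tt, epochs$t_start + config$epoch_s) + 1L
  ok <- tt >= epochs$t_start[1L] & idx <= nrow(epochs)
  out <- data.frame(epoch_index = epochs$epoch_index,
                    vlf_amp_ms = NA_real_, lf_amp_ms = NA_real_,
                    hf_amp_ms = NA_real_, hf_freq_hz = NA_real_,
                    lf_hf = NA_real_)
  if (!any(ok)) return(out)
  for (i in unique(idx[ok])) {
    s <- which(ok & idx == i)
    if (!all(demods$hf$valid[s])) next  # epoch touches an invalid span
    out$vlf_amp_ms[i] <- mean(demods$vlf$amp_ms[s])
    out$lf_amp_ms[i] <- mean(demods$lf$amp_ms[s])
    hf_a <- demods$hf$amp_ms[s]
    out$hf_amp_ms[i] <- mean(hf_a)
    out$hf_freq_hz[i] <- if (sum(hf_a) > 0) {
      sum(hf_a * demods$hf$inst_freq_hz[s]) / sum(hf_a)
    } else demods$hf$f0
    if (out$hf_amp_ms[i] > 0) {
      r <- out$lf_amp_ms[i] / out$hf_amp_ms[i]
      out$lf_hf[i] <- if (config$lfhf_convention == "power") r^2 else r
    }
  }
  out
}

#' HF spectral power concentration index (Hsi)
#'
#' Measures how concentrated the HF-band spectral power is around its peak,
#' a proxy for respiratory-frequency stability. The 2 Hz tachogram is cut
#' into overlapping 256 s (512-point) windows stepped by one 30 s epoch;
#' each window is linearly detrended, Hann-tapered and Fourier transformed
#' (bin width 1/256 Hz). Hsi is 100 times the power within
#' `hsi_halfwidth_bins` bins of the HF peak bin (intersected with the HF
#' band) divided by the total HF-band power, and is assigned to the 30 s
#' epoch at the window centre. Windows extending beyond the record or
#' touching invalid samples give `NA`.
#'
#' @param rs A `"resampled_rr"`.
#' @param epochs Epoch table with `epoch_index`, `t_start`.
#' @param config A [phrv_config()].
#' @return Data.frame with `epoch_index`, `hsi_pct` (0--100 or `NA`).
#' @export
hsi <- function(rs, epochs, config = phrv_config()) {
  stopifnot(inherits(rs, "resampled_rr"))
  npts <- round(config$hsi_window_s * rs$fs)        # 512
  half <- config$hsi_window_s / 2
  w <- config$hsi_halfwidth_bins
  hf <- config$hf_band_hz
  freqs <- (seq_len(npts %/% 2) - 1L) * rs$fs / npts  # 1/256 Hz bins
  hf_bins <- which(freqs >= hf[1L] & freqs <= hf[2L])
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(npts) / (npts + 1))
  out <- data.frame(epoch_index = epochs$epoch_index, hsi_pct = NA_real_)
  centers <- epochs$t_start + config$epoch_s / 2
  for (i in seq_len(nrow(epochs))) {
    t_lo <- centers[i] - half
    k0 <- which.min(abs(rs$t - t_lo))
    if (rs$t[k0] - t_lo > 0.26 || k0 + npts - 1L > length(rs$t)) next
    s <- seq(k0, k0 + npts - 1L)
    if (!all(rs$valid[s])) next
    x <- rs$rr_ms[s]
    tt <- seq_len(npts)
    x <- stats::lm.fit(cbind(1, tt), x)$residuals  # linear detrend
    pw <- Mod(stats::fft(x * hann)[seq_len(npts %/% 2)])^2
    denom <- sum(pw[hf_bins])
    if (denom <= 0) next
    peak <- hf_bins[which.max(pw[hf_bins])]
    sel <- intersect(seq(peak - w, peak + w), hf_bins)
    out$hsi_pct[i] <- 100 * sum(pw[sel]) / denom
  }
  out
}
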