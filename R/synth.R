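# Canonical gravity (reaction) unit vectors per posture, in body axes
# (X toward head, Y toward subject's right, Z out of the chest). The
# reaction vector points skyward: on the back the sky is along +Z, on the
# left side along +Y, upright along +X.
posture_gravity <- c(
  supine        = "0,0,1",
  prone         = "0,0,-1",
  left_lateral  = "0,1,0",
  right_lateral = "0,-1,0",
  upright       = "1,0,0"
)

posture_unit <- function(p) {
  v <- as.numeric(strsplit(posture_gravity[[p]], ",")[[1L]])
  v
}

#' Posture schedule with movement bursts
#'
#' Ground-truth description of a synthetic night: an ordered, non-overlapping
#' sequence of posture intervals plus optional movement bursts.
#'
#' @param postures Data.frame with columns `start_s`, `duration_s`,
#'   `posture` (in supine, right_lateral, left_lateral, prone, upright).
#'   Intervals must be contiguous: truth labels across an uncovered gap
#'   would be undefined.
#' @param movement_bursts Optional data.frame with `start_s`, `duration_s`.
#' @return Object of class `"posture_schedule"`.
#' @export
posture_schedule <- function(postures, movement_bursts = NULL) {
  stopifnot(all(c("start_s", "duration_s", "posture") %in% names(postures)))
  bad <- setdiff(postures$posture, names(posture_gravity))
  if (length(bad) > 0L) {
    stop("unknown posture(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(postures$start_s, strictly = TRUE) && nrow(postures) > 1L) {
    stop("posture intervals must be ordered", call. = FALSE)
  }
  ends <- postures$start_s + postures$duration_s
  if (nrow(postures) > 1L) {
    if (any(abs(postures$start_s[-1L] - ends[-nrow(postures)]) > 1e-9)) {
      stop("posture intervals must be contiguous (no gaps or overlaps)",
           call. = FALSE)
    }
  }
  if (!is.null(movement_bursts)) {
    stopifnot(all(c("start_s", "duration_s") %in% names(movement_bursts)))
  }
  structure(list(postures = postures, movement_bursts = movement_bursts),
            class = "posture_schedule")
}

# random rotation by an angle <= max_deg about a uniformly random axis
random_rotation <- function(max_deg) {
  if (max_deg == 0) return(diag(3))
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a triaxial acceleration series with known posture truth
#'
#' During each posture interval the gravity component is the canonical unit
#' vector of that posture rotated by a fixed random rotation of at most
#' `orientation_jitter_deg` (one rotation drawn per interval, emulating
#' device placement and body obliquity), plus white noise. Movement bursts
#' superimpose a 2.5 Hz oscillation of amplitude `movement_amp_g` on the Y
#' axis. Because a real posture change is itself a body movement, every
#' interior posture boundary additionally gets a burst of
#' `transition_burst_s` seconds centred on it (set it to 0 for idealised
#' instant flips). Truth labels per 30 s epoch are the majority true
#' posture, or `movement` for epochs overlapping a burst.
#'
#' @param schedule A [posture_schedule()].
#' @param noise_sd_g White-noise standard deviation per axis, g.
#' @param orientation_jitter_deg Maximum rotation angle, degrees; must be
#'   below 30 or the truth would be ambiguous near decision boundaries.
#' @param fs Sampling rate, Hz.
#' @param movement_amp_g Amplitude of the movement oscillation (>= 0.03 g so
#'   bursts clear the 20 mG movement threshold).
#' @param transition_burst_s Length of the automatic movement burst at each
#'   interior posture boundary, s.
#' @param start_time Recording start, seconds since midnight.
#' @param seed Optional RNG seed for reproducibility.
#' @return List with `accel` (an [accel_series()]) and `truth` (data.frame
#'   `epoch_index`, `t_start`, `label`).
#' @export
gen_accel <- function(schedule, noise_sd_g = 0.005,
                      orientation_jitter_deg = 10, fs = 31.25,
                      movement_amp_g = 0.05, transition_burst_s = 30,
                      start_time = 0, seed = NULL) {
  stopifnot(inherits(schedule, "posture_schedule"))
  if (orientation_jitter_deg >= 30) {
    stop("orientation jitter must be < 30 degrees", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  po <- schedule$postures
  if (transition_burst_s > 0 && nrow(po) > 1L) {
    bounds <- po$start_s[-1L]
    auto <- data.frame(start_s = bounds - transition_burst_s / 2,
                       duration_s = transition_burst_s)
    mb0 <- schedule$movement_bursts
    schedule$movement_bursts <- if (is.null(mb0)) auto else
      rbind(mb0[, c("start_s", "duration_s")], auto)
  }
  t_end <- po$start_s[nrow(po)] + po$duration_s[nrow(po)]
  t0 <- po$start_s[1L]
  n <- floor((t_end - t0) * fs)
  trel <- (seq_len(n) - 1L) / fs          # time since schedule start
  tabs <- t0 + trel
  g <- matrix(0, n, 3L)
  true_lab <- character(n)
  for (i in seq_len(nrow(po))) {
    sel <- tabs >= po$start_s[i] & tabs < po$start_s[i] + po$duration_s[i]
    vec <- random_rotation(orientation_jitter_deg) %*% posture_unit(po$posture[i])
    g[sel, ] <- matrix(vec, sum(sel), 3L, byrow = TRUE)
    true_lab[sel] <- po$posture[i]
  }
  g <- g + matrix(stats::rnorm(3L * n, sd = noise_sd_g), n, 3L)
  mb <- schedule$movement_bursts
  if (!is.null(mb) && nrow(mb) > 0L) {
    for (i in seq_len(nrow(mb))) {
      on <- mb$start_s[i]
      off <- on + mb$duration_s[i]
      sel <- tabs >= on & tabs < off
      # 1 s on/off ramps keep burst energy out of neighbouring epochs
      env <- pmin(1, tabs[sel] - on, off - tabs[sel])
      g[sel, 2L] <- g[sel, 2L] +
        movement_amp_g * env * sin(2 * pi * 2.5 * tabs[sel])
    }
  }
  accel <- accel_series(g[, 1L], g[, 2L], g[, 3L], fs = fs,
                        start_time = start_time + t0)
  # truth per complete 30 s epoch
  n_ep <- n_epochs(n, fs, 30)
  truth <- data.frame(epoch_index = seq_len(n_ep) - 1L,
                      t_start = start_time + t0 + (seq_len(n_ep) - 1L) * 30,
                      label = NA_character_)
  per <- epoch_split(true_lab, fs, 30)
  for (k in seq_len(n_ep)) {
    tab <- table(per[[k]])
    truth$label[k] <- names(tab)[which.max(tab)]
    ep_lo <- t0 + (k - 1L) * 30
    ep_hi <- ep_lo + 30
    if (!is.null(mb) && nrow(mb) > 0L &&
        any(mb$start_s < ep_hi & mb$start_s + mb$duration_s > ep_lo)) {
      truth$label[k] <- "movement"
    }
  }
  list(accel = accel, truth = truth)
}

#' RR-series generative model
#'
#' Parameters of the synthetic tachogram: a mean level, one sinusoid per
#' HRV band (VLF drift, ~0.1 Hz LF oscillation, respiratory sinus
#' arrhythmia in the HF band with optionally unstable respiratory
#' frequency), trains of transient RR-shortening dips emulating cyclic
#' variation in heart rate, and random ectopic beats.
#'
#' @param mean_rr_ms Mean RR interval, ms.
#' @param vlf,lf Lists `list(amp_ms=, freq_hz=)`; frequencies must lie in
#'   the VLF (0.003--0.04 Hz) and LF (0.04--0.15 Hz) bands.
#' @param hf List `list(amp_ms=, freq_hz=, jitter_sd_hz=)` with `freq_hz`
#'   the respiratory frequency in 0.15--0.40 Hz and `jitter_sd_hz` the
#'   standard deviation of its slow random wander (0 = perfectly stable).
#' @param cvhr `NULL`, or `list(dip_depth_ms=, dip_width_s=, inter_dip_s=,
#'   train_starts=, dips_per_train=, brady=)`: each train starts at a time
#'   in `train_starts` (seconds from the start of the recording, not since
#'   midnight) and holds `dips_per_train` Gaussian dips (full width
#'   at half depth `dip_width_s`) spaced `inter_dip_s` apart; `brady = TRUE`
#'   adds the optional preceding RR-lengthening (bradycardic) phase.
#' @param ectopic_prob Per-beat probability of an ectopic (`V`) beat, < 0.2.
#' @return Object of class `"rr_model"`.
#' @export
rr_model <- function(mean_rr_ms = 1000,
                     vlf = list(amp_ms = 0, freq_hz = 0.02),
                     lf = list(amp_ms = 0, freq_hz = 0.1),
                     hf = list(amp_ms = 0, freq_hz = 0.25, jitter_sd_hz = 0),
                     cvhr = NULL, ectopic_prob = 0) {
  stopifnot(mean_rr_ms > 0, vlf$amp_ms >= 0, lf$amp_ms >= 0, hf$amp_ms >= 0)
  if (vlf$freq_hz < 0.003 || vlf$freq_hz > 0.04) {
    stop("vlf frequency outside 0.003-0.04 Hz", call. = FALSE)
  }
  if (lf$freq_hz < 0.04 || lf$freq_hz > 0.15) {
    stop("lf frequency outside 0.04-0.15 Hz", call. = FALSE)
  }
  if (hf$freq_hz < 0.15 || hf$freq_hz > 0.40) {
    stop("hf frequency outside 0.15-0.40 Hz", call. = FALSE)
  }
  if (ectopic_prob < 0 || ectopic_prob >= 0.2) {
    stop("ectopic_prob must be in [0, 0.2)", call. = FALSE)
  }
  if (is.null(hf$jitter_sd_hz)) hf$jitter_sd_hz <- 0
  if (!is.null(cvhr)) {
    if (is.null(cvhr$dips_per_train)) cvhr$dips_per_train <- 10L
    if (is.null(cvhr$brady)) cvhr$brady <- FALSE
    if (cvhr$dip_depth_ms >= mean_rr_ms) {
      stop("dip depth must be smaller than the mean RR interval",
           call. = FALSE)
    }
  }
  structure(list(mean_rr_ms = mean_rr_ms, vlf = vlf, lf = lf, hf = hf,
                 cvhr = cvhr, ectopic_prob = ectopic_prob),
            class = "rr_model")
}

#' Generate a beat series from an RR model
#'
#' Evaluates the continuous RR trajectory `RR(t) = mean + band sinusoids +
#' dips` and places beats recursively: `beat[k+1] = beat[k] +
#' RR(beat[k]) / 1000`. Dips are negative-going (RR shortening). Ectopic
#' beats get label `V` and their RR shortened by `ectopic_frac` (30%).
#' When the respiratory-frequency jitter is non-zero the HF phase is the
#' integral of a slowly wandering instantaneous frequency (AR(1) with a
#' 30 s correlation time and stationary sd `jitter_sd_hz`, reflected into
#' the HF band).
#'
#' @param model An [rr_model()].
#' @param duration_s Recording length, s; must exceed 600.
#' @param start_time First beat time, seconds since midnight.
#' @param mean_rr_offsets Optional data.frame `start_s`, `end_s`,
#'   `offset_ms` adding a piecewise-constant offset to the mean RR (used by
#'   [gen_cohort()] to inject posture-dependent heart-rate effects).
#' @param ectopic_frac Fractional RR shortening of ectopic beats.
#' @param seed Optional RNG seed.
#' @return List with `beats` (a [beat_series()]) and `truth` (list with the
#'   model, `dip_times`, `ectopic_times`).
#' @export
gen_beats <- function(model, duration_s, start_time = 0,
                      mean_rr_offsets = NULL, ectopic_frac = 0.3,
                      seed = NULL) {
  stopifnot(inherits(model, "rr_model"))
  if (duration_s <= 600) stop("duration_s must exceed 600 s", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # dense grid for the continuous RR trajectory
  dt <- 0.25
  tg <- seq(0, duration_s, by = dt)
  ph <- stats::runif(2, 0, 2 * pi)
  rrg <- rep(model$mean_rr_ms, length(tg))
  rrg <- rrg + model$vlf$amp_ms * sin(2 * pi * model$vlf$freq_hz * tg + ph[1])
  rrg <- rrg + model$lf$amp_ms * sin(2 * pi * model$lf$freq_hz * tg + ph[2])
  if (model$hf$amp_ms > 0) {
    f_inst <- hf_freq_walk(model$hf, tg, dt)
    phase <- 2 * pi * cumsum(f_inst) * dt
    rrg <- rrg + model$hf$amp_ms * sin(phase + stats::runif(1, 0, 2 * pi))
  }
  dip_times <- numeric(0)
  if (!is.null(model$cvhr)) {
    cv <- model$cvhr
    for (ts in cv$train_starts) {
      dip_times <- c(dip_times, ts + (seq_len(cv$dips_per_train) - 1L) *
                       cv$inter_dip_s)
    }
    dip_times <- dip_times[dip_times < duration_s]
    sig <- cv$dip_width_s / (2 * sqrt(2 * log(2)))  # FWHM -> sd
    for (td in dip_times) {
      w <- abs(tg - td) < 4 * sig
      rrg[w] <- rrg[w] - cv$dip_depth_ms * exp(-(tg[w] - td)^2 / (2 * sig^2))
      if (isTRUE(cv$brady)) {
        wb <- abs(tg - (td - cv$dip_width_s)) < 4 * sig
        rrg[wb] <- rrg[wb] + 0.4 * cv$dip_depth_ms *
          exp(-(tg[wb] - (td - cv$dip_width_s))^2 / (2 * sig^2))
      }
    }
  }
  if (!is.null(mean_rr_offsets)) {
    for (i in seq_len(nrow(mean_rr_offsets))) {
      w <- tg >= mean_rr_offsets$start_s[i] & tg < mean_rr_offsets$end_s[i]
      rrg[w] <- rrg[w] + mean_rr_offsets$offset_ms[i]
    }
  }
  if (any(rrg <= 0)) stop("RR trajectory went non-positive", call. = FALSE)
  # place beats (bound allows for ectopic shortening)
  n_max <- ceiling(duration_s /
                     (min(rrg) * (1 - ectopic_frac) / 1000)) + 2L
  bt <- numeric(n_max)
  rr <- numeric(n_max)
  lab <- character(n_max)
  ect <- stats::runif(n_max) < model$ectopic_prob
  t_cur <- 0
  k <- 0L
  while (t_cur < duration_s) {
    k <- k + 1L
    gi <- min(length(tg), max(1L, floor(t_cur / dt) + 1L))
    rr_k <- rrg[gi]
    if (ect[k]) rr_k <- rr_k * (1 - ectopic_frac)
    bt[k] <- t_cur
    rr[k] <- rr_k
    lab[k] <- if (ect[k]) "V" else "N"
    t_cur <- t_cur + rr_k / 1000
  }
  bt <- bt[seq_len(k)]
  lab <- lab[seq_len(k)]
  rr_out <- c(NA_real_, diff(bt) * 1000)
  beats <- beat_series(start_time + bt, rr_out, lab)
  list(beats = beats,
       truth = list(model = model, dip_times = start_time + dip_times,
                    ectopic_times = start_time + bt[lab == "V"]))
}

# slowly wandering instantaneous respiratory frequency (AR(1), tau = 30 s),
# reflected at the HF band edges
hf_freq_walk <- function(hf, tg, dt) {
  n <- length(tg)
  if (hf$jitter_sd_hz <= 0) return(rep(hf$freq_hz, n))
  rho <- exp(-dt / 30)
  e <- stats::rnorm(n, sd = hf$jitter_sd_hz * sqrt(1 - rho^2))
  dev <- numeric(n)
  dev[1L] <- stats::rnorm(1, sd = hf$jitter_sd_hz)
  for (i in 2:n) dev[i] <- rho * dev[i - 1L] + e[i]
  f <- hf$freq_hz + dev
  lo <- 0.15; hi <- 0.40
  f <- abs(f - lo) + lo          # reflect at lower edge
  f <- hi - abs(hi - f)          # and upper edge
  pmax(lo, pmin(hi, f))
}
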