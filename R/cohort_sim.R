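#' Simulate a cohort of synthetic nights with known ground truth
#'
#' Generates, for each subject, a nighttime posture schedule (contiguous
#' bouts of the four lying postures aligned to the 30 s epoch grid, with
#' occasional movement bursts), the matching triaxial acceleration series,
#' and a beat series whose mean RR follows the schedule so that
#' posture-dependent heart-rate effects can be injected and later recovered
#' by the pipeline. Every generating parameter is recorded in the returned
#' truth table.
#'
#' @param n_subjects Number of subjects; at least 4 (two groups of two) so
#'   downstream group statistics are defined.
#' @param age_bins Age decades to draw subjects from (uniform age within the
#'   decade, decades equally likely).
#' @param posture_pref Named sampling weights for the four lying postures.
#' @param index_effects List of injected effects. Supported:
#'   `hr_offset_bpm`, a named numeric vector of per-posture heart-rate
#'   offsets in bpm (e.g. `c(left_lateral = -3)`).
#' @param duration_h Night length in hours starting at 22:00.
#' @param hr_base_mean,hr_base_sd Between-subject distribution of the basal
#'   heart rate, bpm.
#' @param apnea_frac Fraction of subjects given nightly CVHR dip trains
#'   (12 trains of 10 dips, depth 150 ms, width 30 s, 60 s spacing, enough
#'   to cross the 15/h severity cutoff).
#' @param ectopic_prob Per-beat ectopy probability.
#' @param jitter_deg,noise_sd_g Orientation jitter and accelerometer noise
#'   passed to [gen_accel()].
#' @param seed RNG seed for the whole cohort.
#' @param write_dir Optional directory: per-subject `*_accel.csv` /
#'   `*_beats.csv`, a `meta.csv` and a `truth.csv` are written there.
#' @return List with `subjects` (list of `list(accel, beats, meta)`) and
#'   `truth` (data.frame of per-subject generating parameters).
#' @export
gen_cohort <- function(n_subjects,
                       age_bins = c(40, 70),
                       posture_pref = c(supine = 0.4, right_lateral = 0.25,
                                        left_lateral = 0.25, prone = 0.1),
                       index_effects = list(),
                       duration_h = 6,
                       hr_base_mean = 62, hr_base_sd = 4,
                       apnea_frac = 0,
                       ectopic_prob = 0.02,
                       jitter_deg = 8, noise_sd_g = 0.005,
                       seed = NULL, write_dir = NULL) {
  if (n_subjects < 4L) {
    stop("need at least 4 subjects (2 groups x 2 subjects)", call. = FALSE)
  }
  stopifnot(all(names(posture_pref) %in% lying_postures))
  if (!is.null(seed)) set.seed(seed)
  hr_off <- index_effects$hr_offset_bpm %||% numeric(0)
  t0 <- 22 * 3600
  dur_s <- duration_h * 3600
  subjects <- vector("list", n_subjects)
  truth <- data.frame(subject_id = character(n_subjects),
                      age = numeric(n_subjects),
                      sex = character(n_subjects),
                      hr_base_bpm = numeric(n_subjects),
                      apnea = logical(n_subjects),
                      n_dips = integer(n_subjects),
                      stringsAsFactors = FALSE)
  for (s in seq_len(n_subjects)) {
    id <- sprintf("S%03d", s)
    age <- age_bins[sample.int(length(age_bins), 1L)] + stats::runif(1, 0, 10)
    sex <- sample(c("female", "male"), 1L)
    hr_base <- stats::rnorm(1, hr_base_mean, hr_base_sd)
    sched <- random_night_schedule(t0, dur_s, posture_pref)
    acc <- gen_accel(sched, noise_sd_g = noise_sd_g,
                     orientation_jitter_deg = jitter_deg,
                     start_time = 0)
    offs <- posture_hr_offsets(sched, hr_base, hr_off)
    apnea <- stats::runif(1) < apnea_frac
    cv <- NULL
    if (apnea) {
      cv <- list(dip_depth_ms = 150, dip_width_s = 30, inter_dip_s = 60,
                 train_starts = seq(600, dur_s - 900, length.out = 12),
                 dips_per_train = 10L)
    }
    model <- rr_model(
      mean_rr_ms = 60000 / hr_base,
      vlf = list(amp_ms = stats::runif(1, 20, 40), freq_hz = 0.02),
      lf = list(amp_ms = stats::runif(1, 15, 30), freq_hz = 0.1),
      hf = list(amp_ms = stats::runif(1, 20, 40),
                freq_hz = stats::runif(1, 0.20, 0.30),
                jitter_sd_hz = 0.01),
      cvhr = cv, ectopic_prob = ectopic_prob
    )
    gb <- gen_beats(model, dur_s, start_time = t0, mean_rr_offsets = offs)
    meta <- list(subject_id = id, age = age, sex = sex)
    subjects[[s]] <- list(accel = acc$accel, beats = gb$beats, meta = meta,
                          posture_truth = acc$truth)
    truth$subject_id[s] <- id
    truth$age[s] <- age
    truth$sex[s] <- sex
    truth$hr_base_bpm[s] <- hr_base
    truth$apnea[s] <- apnea
    truth$n_dips[s] <- length(gb$truth$dip_times)
  }
  for (p in names(hr_off)) truth[[paste0("hr_offset_", p)]] <- hr_off[[p]]
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    meta_rows <- lapply(subjects, function(su) as.data.frame(su$meta))
    utils::write.csv(do.call(rbind, meta_rows),
                     file.path(write_dir, "meta.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(write_dir, "truth.csv"),
                     row.names = FALSE)
    for (su in subjects) {
      write_accel(su$accel,
                  file.path(write_dir, paste0(su$meta$subject_id, "_accel.csv")))
      write_beats(su$beats,
                  file.path(write_dir, paste0(su$meta$subject_id, "_beats.csv")))
    }
  }
  list(subjects = subjects, truth = truth)
}

# contiguous epoch-aligned posture bouts; the first four bouts cover all
# four postures so every subject has enough epochs per posture
random_night_schedule <- function(t0, dur_s, pref) {
  postures <- character(0)
  durs <- numeric(0)
  first <- sample(lying_postures)
  for (p in first) {
    postures <- c(postures, p)
    durs <- c(durs, 30 * sample(24:50, 1L))  # 12-25 min
  }
  while (sum(durs) < dur_s) {
    p <- sample(names(pref), 1L, prob = pref)
    if (p == postures[length(postures)]) next
    postures <- c(postures, p)
    durs <- c(durs, 30 * sample(24:60, 1L))
  }
  total <- cumsum(durs)
  cut <- which(total >= dur_s)[1L]
  postures <- postures[seq_len(cut)]
  durs <- durs[seq_len(cut)]
  durs[cut] <- durs[cut] - (sum(durs) - dur_s)
  starts <- t0 + c(0, cumsum(durs))[seq_along(durs)]
  # one 30 s movement burst per ~2 h, epoch-aligned inside a bout
  n_b <- max(0L, round(dur_s / 7200))
  bursts <- NULL
  if (n_b > 0L) {
    bs <- t0 + 30 * sample(seq_len(dur_s %/% 30 - 2L), n_b)
    bursts <- data.frame(start_s = sort(bs), duration_s = 30)
  }
  posture_schedule(
    data.frame(start_s = starts, duration_s = durs, posture = postures,
               stringsAsFactors = FALSE),
    movement_bursts = bursts
  )
}

# piecewise-constant mean-RR offsets implementing per-posture HR offsets
posture_hr_offsets <- function(sched, hr_base, hr_off) {
  if (length(hr_off) == 0L) return(NULL)
  po <- sched$postures
  off <- vapply(po$posture, function(p) {
    o <- unname(hr_off[p])
    if (is.na(o)) 0 else 60000 / (hr_base + o) - 60000 / hr_base
  }, numeric(1))
  keep <- off != 0
  if (!any(keep)) return(NULL)
  data.frame(start_s = po$start_s[keep] - po$start_s[1L],
             end_s = po$start_s[keep] + po$duration_s[keep] - po$start_s[1L],
             offset_ms = off[keep])
}
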