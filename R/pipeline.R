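#' Analyse one subject end-to-end
#'
#' Runs the full per-subject chain: posture classification of the
#' acceleration series into 30 s epochs, NN-interval extraction, per-epoch
#' HRV indices, optional complex-demodulation band indices and Hsi, CVHR
#' apnea screening, nighttime eligibility, and per-posture aggregation.
#'
#' @param accel An [accel_series()].
#' @param beats A [beat_series()].
#' @param meta Optional list with `subject_id`, `age`, `sex`.
#' @param config A [phrv_config()].
#' @param compute Character subset of `c("time", "freq", "hsi", "cvhr")`
#'   selecting which index families to compute (posture classification and
#'   eligibility always run).
#' @param verbose Log pipeline stages.
#' @return Object of class `"subject_record"`: list with `meta`, `epochs`
#'   (merged epoch table), `eligibility`, `posture_pct`, `per_posture`
#'   (per-posture index means), `cvhr_rate`, `screen` (the
#'   `"apnea_screen"`, or `NULL`), `config`.
#' @export
analyze_subject <- function(accel, beats, meta = NULL,
                            config = phrv_config(),
                            compute = c("time", "freq", "hsi", "cvhr"),
                            verbose = FALSE) {
  compute <- match.arg(compute, several.ok = TRUE)
  ep <- classify_posture(accel, config, verbose = verbose)
  nn <- suppressWarnings(extract_nn(beats))
  have_nn <- length(nn$time) >= 4L
  if ("time" %in% compute && have_nn) {
    log_stage("time_domain", config["min_nn_per_epoch"], verbose)
    ep <- merge(ep, epoch_hr_sdrr(nn, ep, config), by = "epoch_index")
  }
  rs <- NULL
  if (have_nn && any(c("freq", "hsi", "cvhr") %in% compute)) {
    rs <- resample_2hz(nn, config)
  }
  if ("freq" %in% compute && have_nn) {
    log_stage("demodulation",
              config[c("vlf_band_hz", "lf_band_hz", "hf_band_hz",
                       "lfhf_convention")], verbose)
    demods <- list(vlf = complex_demodulate(rs, "VLF", config),
                   lf = complex_demodulate(rs, "LF", config),
                   hf = complex_demodulate(rs, "HF", config))
    ep <- merge(ep, epoch_band_stats(demods, ep, config), by = "epoch_index")
  }
  if ("hsi" %in% compute && have_nn) {
    log_stage("hsi", config[c("hsi_window_s", "hsi_halfwidth_bins")], verbose)
    ep <- merge(ep, hsi(rs, ep, config), by = "epoch_index")
  }
  scr <- NULL
  if ("cvhr" %in% compute && have_nn &&
      diff(range(nn$time)) >= 600) {
    log_stage("cvhr", config[c("cvhr_baseline_s", "cvhr_depth_min_ms",
                               "ahi_severity_cutoff")], verbose)
    scr <- screen_cvhr(nn, ep, config)
    ep <- merge(ep, scr$epoch_flags, by = "epoch_index")
  }
  elig <- eligibility(ep, beats, config)
  pct <- suppressWarnings(posture_percentages(ep$label))
  per_post <- NULL
  cv_rate <- NULL
  if (elig$eligible) {
    per_post <- per_posture_means(ep, config = config)
    if (!is.null(scr)) cv_rate <- cvhr_rate_per_posture(ep, config)
  }
  structure(
    list(meta = meta, epochs = ep, eligibility = elig, posture_pct = pct,
         per_posture = per_post, cvhr_rate = cv_rate, screen = scr,
         config = config),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  id <- if (!is.null(x$meta$subject_id)) x$meta$subject_id else "?"
  cat(sprintf("<subject_record> %s: %d epochs, eligible: %s (%s)\n",
              id, nrow(x$epochs), x$eligibility$eligible,
              x$eligibility$reason))
  if (!all(is.na(x$posture_pct))) {
    cat("  posture %:",
        paste(sprintf("%s %.1f", names(x$posture_pct), x$posture_pct),
              collapse = ", "), "\n")
  }
  if (!is.null(x$screen) && !is.na(x$screen$ahi_est)) {
    cat(sprintf("  estimated AHI %.1f /h (%s)\n", x$screen$ahi_est,
                x$screen$severity))
  }
  invisible(x)
}

#' @export
summary.subject_record <- function(object, ...) {
  print(object)
  if (!is.null(object$per_posture)) {
    cat("per-posture means:\n")
    print(object$per_posture, digits = 4)
  }
  invisible(object)
}

#' @export
plot.subject_record <- function(x, index = "hr_bpm", ...) {
  ep <- x$epochs
  if (!index %in% names(ep)) stop("index column not present: ", index)
  cols <- c(supine = "skyblue3", right_lateral = "seagreen",
            left_lateral = "blue3", prone = "navy", movement = "grey60",
            transition = "grey80", non_lying = "tan")
  graphics::plot((ep$t_start - ep$t_start[1]) / 3600, ep[[index]],
                 col = cols[ep$label], pch = 16, cex = 0.6,
                 xlab = "hours from start", ylab = index, ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   cex = 0.6, bty = "n")
  invisible(x)
}

#' Long-format table of per-subject per-posture means
#'
#' Collects eligible subjects' per-posture index means into the long format
#' consumed by [stratified_table()] and [posture_rm_anova()].
#'
#' @param records List of `"subject_record"` objects.
#' @return Data.frame with `subject_id`, `sex`, `age10`, `posture` and one
#'   column per index.
#' @export
cohort_long <- function(records) {
  rows <- list()
  for (r in records) {
    if (!isTRUE(r$eligibility$eligible) || is.null(r$per_posture)) next
    pp <- r$per_posture
    d <- data.frame(
      subject_id = r$meta$subject_id %||% NA_character_,
      sex = r$meta$sex %||% NA_character_,
      age10 = if (!is.null(r$meta$age)) age10(r$meta$age) else NA_integer_,
      posture = pp$posture,
      stringsAsFactors = FALSE
    )
    for (col in setdiff(names(pp), c("posture", "n_epochs"))) {
      d[[col]] <- pp[[col]]
    }
    d$posture_pct <- unname(r$posture_pct[pp$posture])
    if (!is.null(r$cvhr_rate)) d$cvhr_rate <- unname(r$cvhr_rate[pp$posture])
    if (!is.null(r$screen)) {
      d$ahi_est <- r$screen$ahi_est
      d$severity <- r$screen$severity
    }
    rows[[length(rows) + 1L]] <- d
  }
  if (length(rows) == 0L) {
    stop("no eligible subjects", call. = FALSE)
  }
  nm <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(d) {
    for (m in setdiff(nm, names(d))) d[[m]] <- NA
    d[, nm]
  })
  do.call(rbind, rows)
}

#' Analyse a cohort of subjects
#'
#' Applies [analyze_subject()] to every subject, keeps the eligible ones,
#' and produces the stratified cohort table plus repeated-measures posture
#' tests per index.
#'
#' @param subjects List; each element a list with `accel`, `beats`, `meta`.
#' @param config A [phrv_config()].
#' @param compute Index families to compute, as in [analyze_subject()].
#' @param indices Index columns to test for a posture effect; default
#'   `"hr_bpm"` plus whatever else is present.
#' @return Object of class `"cohort_analysis"`: list with `records`,
#'   `long`, `table` (a `"cohort_table"`), `anova` (named list of
#'   [posture_rm_anova()] results).
#' @export
analyze_cohort <- function(subjects, config = phrv_config(),
                           compute = c("time", "freq", "hsi", "cvhr"),
                           indices = NULL) {
  records <- lapply(subjects, function(s) {
    analyze_subject(s$accel, s$beats, s$meta, config, compute = compute)
  })
  long <- cohort_long(records)
  tab <- stratified_table(long)
  if (is.null(indices)) {
    indices <- intersect(c("hr_bpm", "sdrr_ms", "vlf_amp_ms", "lf_amp_ms",
                           "hf_amp_ms", "hf_freq_hz", "lf_hf", "hsi_pct",
                           "cvhr_rate"),
                         names(long))
  }
  anv <- list()
  for (col in indices) {
    wide <- stats::reshape(
      long[, c("subject_id", "posture", col)],
      idvar = "subject_id", timevar = "posture", direction = "wide")
    m <- as.matrix(wide[, -1L, drop = FALSE])
    colnames(m) <- sub(paste0("^", col, "\\."), "", colnames(m))
    grp <- long$age10[match(wide$subject_id, long$subject_id)]
    anv[[col]] <- posture_rm_anova(m, group = grp)
  }
  structure(list(records = records, long = long, table = tab, anova = anv),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d subjects analysed, %d eligible\n",
              length(x$records),
              length(unique(x$long$subject_id))))
  for (nm in names(x$anova)) {
    a <- x$anova[[nm]]
    cat(sprintf("  %-12s posture F=%.2f p=%.3g (n=%d complete)\n",
                nm, a$F_posture, a$p_posture, a$n_subjects))
  }
  invisible(x)
}
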