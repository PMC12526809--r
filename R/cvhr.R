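#' Detect transient RR-shortening dips (CVHR candidates)
#'
#' Cyclic variation in heart rate shows up as trains of transient heart-rate
#' accelerations, i.e. dips of the RR tachogram below its slow baseline.
#' The detector resamples the NN series at 2 Hz, removes respiratory-band
#' oscillation with a `cvhr_smooth_hz` (0.1 Hz) zero-phase low-pass (a
#' 10--120 s dip passes essentially intact while respiratory sinus
#' arrhythmia would otherwise masquerade as narrow deep excursions),
#' subtracts a `cvhr_baseline_s` (130 s) moving-median baseline, and keeps
#' excursions whose depth below baseline reaches `cvhr_depth_min_ms`
#' (50 ms) and whose full width at half depth lies within `cvhr_width_s`
#' (10--120 s). Nadirs on invalid (gap-bridged) spans are discarded.
#'
#' @param nn An `"nn_series"` from [extract_nn()].
#' @param config A [phrv_config()].
#' @return Data.frame of dip events: `nadir_time` (s), `depth_ms`,
#'   `width_s`, `member_of_train` (initialised `FALSE`; see
#'   [cluster_trains()]).
#' @export
detect_dips <- function(nn, config = phrv_config()) {
  if (length(nn$time) < 2L ||
      diff(range(nn$time)) < 600) {
    stop("need at least 10 min of NN data for CVHR detection", call. = FALSE)
  }
  rs <- resample_2hz(nn, config)
  x <- butter_lowpass(rs$rr_ms, rs$fs, config$cvhr_smooth_hz)
  k <- round(config$cvhr_baseline_s * rs$fs)
  if (k %% 2L == 0L) k <- k + 1L
  baseline <- stats::runmed(x, k, endrule = "median")
  d <- x - baseline
  empty <- data.frame(nadir_time = numeric(0), depth_ms = numeric(0),
                      width_s = numeric(0), member_of_train = logical(0))
  below <- d <= -config$cvhr_depth_min_ms
  if (!any(below)) return(empty)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_s <- starts[r$values]
  seg_e <- ends[r$values]
  # residual ripple can split one dip into two threshold crossings; merge
  # regions closer than half the minimum inter-dip interval, which no pair
  # of genuine dips can approach
  merge_gap <- config$cvhr_interdip_s[1L] / 2 * rs$fs
  merged_s <- seg_s[1L]
  merged_e <- seg_e[1L]
  if (length(seg_s) > 1L) {
    for (j in 2:length(seg_s)) {
      if (seg_s[j] - merged_e[length(merged_e)] < merge_gap) {
        merged_e[length(merged_e)] <- seg_e[j]
      } else {
        merged_s <- c(merged_s, seg_s[j])
        merged_e <- c(merged_e, seg_e[j])
      }
    }
  }
  out <- empty
  for (seg in seq_along(merged_s)) {
    s <- seq(merged_s[seg], merged_e[seg])
    nadir <- s[which.min(d[s])]
    if (!rs$valid[nadir]) next
    depth <- -d[nadir]
    halfd <- -depth / 2
    left <- nadir
    while (left > 1L && d[left - 1L] <= halfd) left <- left - 1L
    right <- nadir
    n <- length(d)
    while (right < n && d[right + 1L] <= halfd) right <- right + 1L
    width <- (right - left) / rs$fs
    if (width < config$cvhr_width_s[1L] || width > config$cvhr_width_s[2L]) next
    out <- rbind(out, data.frame(nadir_time = rs$t[nadir], depth_ms = depth,
                                 width_s = width, member_of_train = FALSE))
  }
  out[order(out$nadir_time), , drop = FALSE]
}

#' Mark dips that form cyclic trains
#'
#' A dip only counts as CVHR when it recurs cyclically. Consecutive dips are
#' linked when their inter-dip interval falls in `cvhr_interdip_s`
#' (25--130 s); a run of links is broken where the ratio of neighbouring
#' intervals leaves `cvhr_ratio_range` (0.5--2). Every dip in a run of at
#' least three dips (so each member has at least two companions at
#' compatible spacing) is flagged as a train member.
#'
#' @param dips Data.frame from [detect_dips()], sorted by `nadir_time`.
#' @param config A [phrv_config()].
#' @return The same data.frame with `member_of_train` filled in.
#' @export
cluster_trains <- function(dips, config = phrv_config()) {
  n <- nrow(dips)
  dips$member_of_train <- rep(FALSE, n)
  if (n < 3L) return(dips)
  if (is.unsorted(dips$nadir_time)) {
    stop("dips must be sorted by nadir_time", call. = FALSE)
  }
  gap <- diff(dips$nadir_time)
  link <- gap >= config$cvhr_interdip_s[1L] & gap <= config$cvhr_interdip_s[2L]
  # break runs where neighbouring inter-dip intervals are incompatible
  run_id <- integer(n - 1L)
  cur <- 0L
  for (j in seq_len(n - 1L)) {
    if (!link[j]) { run_id[j] <- 0L; next }
    if (j > 1L && link[j - 1L] && run_id[j - 1L] > 0L) {
      ratio <- gap[j] / gap[j - 1L]
      if (ratio >= config$cvhr_ratio_range[1L] &&
          ratio <= config$cvhr_ratio_range[2L]) {
        run_id[j] <- run_id[j - 1L]
        next
      }
    }
    cur <- cur + 1L
    run_id[j] <- cur
  }
  for (id in setdiff(unique(run_id), 0L)) {
    links <- which(run_id == id)
    if (length(links) >= 2L) {  # >= 3 dips
      dips$member_of_train[c(links, links[length(links)] + 1L)] <- TRUE
    }
  }
  dips
}

#' Screen a subject for sleep apnea from CVHR
#'
#' Detects dips on the full NN record, clusters them into trains, and counts
#' train-member dips whose nadir falls inside nighttime lying epochs. The
#' estimated apnea--hypopnea index (AHI) is that count divided by the hours
#' spent in lying epochs; subjects at or above `ahi_severity_cutoff` (15/h)
#' are classified `moderate_to_severe`, below it `normal_to_mild`. Each
#' 30 s epoch is additionally flagged sleep-apnea-positive when at least one
#' train-member nadir falls inside it.
#'
#' @param nn An `"nn_series"`.
#' @param epochs Epoch table with `epoch_index`, `t_start`, `label`.
#' @param config A [phrv_config()].
#' @return An object of class `"apnea_screen"`: list with `ahi_est` (per
#'   hour; `NA` when the subject has no lying epochs), `severity`,
#'   `lying_hours`, `dips` (the dip table) and `epoch_flags` (data.frame
#'   `epoch_index`, `cvhr_positive`).
#' @export
screen_cvhr <- function(nn, epochs, config = phrv_config()) {
  dips <- cluster_trains(detect_dips(nn, config), config)
  members <- dips[dips$member_of_train, , drop = FALSE]
  lying <- epochs$label %in% lying_postures
  lying_hours <- sum(lying) * config$epoch_s / 3600
  in_epoch <- function(tt) {
    i <- findInterval(tt, epochs$t_start + config$epoch_s) + 1L
    i[tt < epochs$t_start[1L] | i > nrow(epochs)] <- NA_integer_
    i
  }
  flags <- data.frame(epoch_index = epochs$epoch_index,
                      cvhr_positive = FALSE)
  m_idx <- in_epoch(members$nadir_time)
  flags$cvhr_positive[unique(m_idx[!is.na(m_idx)])] <- TRUE
  if (lying_hours == 0) {
    warning("no lying epochs: estimated AHI undefined")
    ahi <- NA_real_
    sev <- NA_character_
  } else {
    n_lying_dips <- sum(!is.na(m_idx) & lying[m_idx])
    ahi <- n_lying_dips / lying_hours
    sev <- if (ahi >= config$ahi_severity_cutoff) {
      "moderate_to_severe"
    } else "normal_to_mild"
  }
  structure(
    list(ahi_est = ahi, severity = sev, lying_hours = lying_hours,
         dips = dips, epoch_flags = flags),
    class = "apnea_screen"
  )
}

#' @export
print.apnea_screen <- function(x, ...) {
  cat(sprintf(
    "<apnea_screen> AHI %.2f /h (%s), %d train dips / %d dips, %.2f lying h\n",
    x$ahi_est, x$severity, sum(x$dips$member_of_train), nrow(x$dips),
    x$lying_hours
  ))
  invisible(x)
}
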