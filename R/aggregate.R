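#' Nighttime eligibility of a recording
#'
#' A subject enters the analysis only when (i) more than `min_lying_h`
#' (5) hours of posture-labelled lying epochs fall inside the night window
#' (22:00--08:00 by default; epoch membership by its start time) and (ii)
#' at least `min_sinus_frac` (80%) of the nighttime lying data is in sinus
#' rhythm. The sinus fraction is the fraction of beats labelled `N` inside
#' those lying epochs (`sinus_frac_basis = "beats"`), or the fraction of
#' time covered by NN intervals (`"time"`).
#'
#' @param epochs Epoch table with `t_start` and `label`.
#' @param beats A [beat_series()].
#' @param config A [phrv_config()].
#' @return List with `eligible` (logical), `reason` (`"ok"`, `"lying<5h"`
#'   or `"sinus<80%"`), `lying_h`, `sinus_frac`.
#' @export
eligibility <- function(epochs, beats, config = phrv_config()) {
  nw <- config$night_window_s
  lying <- epochs$label %in% lying_postures &
    epochs$t_start >= nw[1L] & epochs$t_start < nw[2L]
  lying_h <- sum(lying) * config$epoch_s / 3600
  if (lying_h <= config$min_lying_h) {
    return(list(eligible = FALSE,
                reason = sprintf("lying<%gh", config$min_lying_h),
                lying_h = lying_h, sinus_frac = NA_real_))
  }
  starts <- epochs$t_start[lying]
  in_lying <- rep(FALSE, length(beats$beat_time))
  for (s in starts) {
    in_lying <- in_lying |
      (beats$beat_time >= s & beats$beat_time < s + config$epoch_s)
  }
  if (!any(in_lying)) {
    sf <- 0
  } else if (config$sinus_frac_basis == "beats") {
    sf <- mean(beats$label[in_lying] == "N")
  } else {
    n <- length(beats$beat_time)
    nn_int <- c(FALSE, beats$label[-1L] == "N" & beats$label[-n] == "N")
    sf <- sum(beats$rr_ms[in_lying & nn_int], na.rm = TRUE) /
      sum(beats$rr_ms[in_lying], na.rm = TRUE)
  }
  if (sf < config$min_sinus_frac) {
    return(list(eligible = FALSE,
                reason = sprintf("sinus<%g%%", 100 * config$min_sinus_frac),
                lying_h = lying_h, sinus_frac = sf))
  }
  list(eligible = TRUE, reason = "ok", lying_h = lying_h, sinus_frac = sf)
}

#' Per-posture means of epoch HRV indices
#'
#' Groups the per-epoch indices by the epoch's posture label and averages
#' each index over the epochs of that posture, skipping `NA` epochs. A
#' posture with fewer than `min_epochs_per_posture` epochs gets `NA` means.
#'
#' @param epoch_table Merged epoch table: posture labels plus index columns.
#' @param index_cols Character vector of index column names; defaults to
#'   every numeric column other than the bookkeeping ones.
#' @param config A [phrv_config()].
#' @return Data.frame: one row per lying posture, columns `posture`,
#'   `n_epochs`, then one column per index.
#' @export
per_posture_means <- function(epoch_table, index_cols = NULL,
                              config = phrv_config()) {
  if (is.null(index_cols)) {
    skip <- c("epoch_index", "t_start", "movement", "theta_x", "theta_y",
              "theta_z", "n_nn", "cvhr_positive")
    index_cols <- setdiff(
      names(epoch_table)[vapply(epoch_table, is.numeric, logical(1))], skip)
  }
  out <- data.frame(posture = lying_postures, n_epochs = 0L,
                    stringsAsFactors = FALSE)
  for (col in index_cols) out[[col]] <- NA_real_
  for (i in seq_along(lying_postures)) {
    rows <- epoch_table$label == lying_postures[i]
    out$n_epochs[i] <- sum(rows)
    if (sum(rows) < config$min_epochs_per_posture) next
    for (col in index_cols) {
      v <- epoch_table[[col]][rows]
      out[[col]][i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
  }
  out
}

#' CVHR rate per posture
#'
#' The number of sleep-apnea-positive epochs in each posture divided by the
#' hours spent in that posture. Postures without epochs get `NA`.
#'
#' @param epoch_table Epoch table with `label` and `cvhr_positive`.
#' @param config A [phrv_config()].
#' @return Named numeric vector (per hour) over the four lying postures.
#' @export
cvhr_rate_per_posture <- function(epoch_table, config = phrv_config()) {
  out <- stats::setNames(rep(NA_real_, 4L), lying_postures)
  for (p in lying_postures) {
    rows <- epoch_table$label == p
    hours <- sum(rows) * config$epoch_s / 3600
    if (hours > 0) out[p] <- sum(epoch_table$cvhr_positive[rows]) / hours
  }
  out
}
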