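#' Analysis parameters
#'
#' Build the full set of pipeline parameters. Every tunable threshold in the
#' pipeline lives here; unspecified values take the published defaults.
#'
#' @details
#' Parameter groups and defaults:
#'
#' *Posture classification*
#' \describe{
#'   \item{movement_threshold_g}{0.020 g. A 30 s epoch is a movement epoch
#'     when the peak magnitude of the 2--3 Hz band-passed composite
#'     acceleration vector reaches this value (20 mG).}
#'   \item{move_band_hz}{c(2, 3). Band-pass edges (Hz) isolating body
#'     movement from the raw acceleration.}
#'   \item{gravity_corner_hz}{0.1. Low-pass corner (Hz) extracting the
#'     gravitational component.}
#'   \item{lying_center_deg, lying_halfwidth_deg}{84 and 36. Lying is
#'     declared when the head--foot axis makes an angle of 84 +/- 36 degrees
#'     with the gravity vector, i.e. theta_X in \[48, 120\].}
#'   \item{left_lateral_deg, right_lateral_deg}{65 and 111. Within lying,
#'     theta_Y < 65 is left lateral and theta_Y > 111 is right lateral.}
#'   \item{supine_deg}{60. Remaining lying samples are supine when
#'     theta_Z < 60, otherwise prone.}
#'   \item{majority_frac}{0.5. An epoch takes a posture label only when a
#'     single posture exceeds this fraction of its samples; otherwise it is a
#'     transition epoch.}
#'   \item{epoch_s}{30. Epoch length in seconds.}
#' }
#'
#' *HRV indices*
#' \describe{
#'   \item{vlf_band_hz, lf_band_hz, hf_band_hz}{c(0.003, 0.04),
#'     c(0.04, 0.15), c(0.15, 0.40) Hz.}
#'   \item{lfhf_convention}{"power" (squared amplitude ratio) or
#'     "amplitude".}
#'   \item{resample_hz}{2. Rate for the cubic-spline resampled NN series.}
#'   \item{min_nn_per_epoch}{10. Minimum NN intervals for per-epoch HR/SDRR.}
#'   \item{max_gap_s}{5. NN gaps longer than this invalidate overlapping
#'     resampled spans.}
#'   \item{hsi_window_s, hsi_halfwidth_bins}{256 s (512 points) FFT windows
#'     stepped by one epoch; Hsi sums power within +/- 5 bins (about
#'     +/- 0.0195 Hz) of the HF spectral peak.}
#' }
#'
#' *CVHR / apnea screening*
#' \describe{
#'   \item{cvhr_smooth_hz}{0.1. Low-pass corner removing respiratory
#'     oscillation from the tachogram before dip detection.}
#'   \item{cvhr_baseline_s}{130. Moving-median baseline window (s).}
#'   \item{cvhr_depth_min_ms}{50. Minimum dip depth below baseline.}
#'   \item{cvhr_width_s}{c(10, 120). Accepted full width at half depth.}
#'   \item{cvhr_interdip_s}{c(25, 130). Inter-dip intervals forming a train.}
#'   \item{cvhr_ratio_range}{c(0.5, 2). Allowed ratio of neighbouring
#'     inter-dip intervals within a train.}
#'   \item{ahi_severity_cutoff}{15. Estimated AHI (dips per lying hour) at or
#'     above this is moderate-to-severe sleep apnea.}
#' }
#'
#' *Eligibility and aggregation*
#' \describe{
#'   \item{night_window_s}{c(79200, 115200): 22:00 to 08:00 next day, in
#'     seconds since midnight (times past midnight continue beyond 86400).}
#'   \item{min_lying_h}{5. Required lying time within the night window.}
#'   \item{min_sinus_frac}{0.80. Required fraction of sinus (N) beats within
#'     nighttime lying epochs.}
#'   \item{min_epochs_per_posture}{10. A per-posture mean is reported only
#'     with at least this many epochs.}
#'   \item{sinus_frac_basis}{"beats" (fraction of beats labelled N) or
#'     "time" (fraction of NN time).}
#' }
#'
#' @param ... named overrides of the defaults listed above.
#' @return A named list of parameters with class `"phrv_config"`.
#' @seealso [load_config()] to read overrides from a YAML file.
#' @export
#' @examples
#' cfg <- phrv_config(movement_threshold_g = 0.025)
#' cfg$movement_threshold_g
phrv_config <- function(...) {
  cfg <- list(
    # posture
    movement_threshold_g   = 0.020,
    move_band_hz           = c(2, 3),
    gravity_corner_hz      = 0.1,
    lying_center_deg       = 84,
    lying_halfwidth_deg    = 36,
    left_lateral_deg       = 65,
    right_lateral_deg      = 111,
    supine_deg             = 60,
    majority_frac          = 0.5,
    epoch_s                = 30,
    # hrv
    vlf_band_hz            = c(0.003, 0.04),
    lf_band_hz             = c(0.04, 0.15),
    hf_band_hz             = c(0.15, 0.40),
    lfhf_convention        = "power",
    resample_hz            = 2,
    min_nn_per_epoch       = 10,
    max_gap_s              = 5,
    hsi_window_s           = 256,
    hsi_halfwidth_bins     = 5,
    # cvhr
    cvhr_smooth_hz         = 0.1,
    cvhr_baseline_s        = 130,
    cvhr_depth_min_ms      = 50,
    cvhr_width_s           = c(10, 120),
    cvhr_interdip_s        = c(25, 130),
    cvhr_ratio_range       = c(0.5, 2),
    ahi_severity_cutoff    = 15,
    # eligibility / aggregation
    night_window_s         = c(22 * 3600, 32 * 3600),
    min_lying_h            = 5,
    min_sinus_frac         = 0.80,
    min_epochs_per_posture = 10,
    sinus_frac_basis       = "beats"
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1L]]
  }
  cfg <- apply_overrides(cfg, overrides)
  class(cfg) <- "phrv_config"
  cfg
}

apply_overrides <- function(cfg, overrides) {
  if (length(overrides) == 0L) return(cfg)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == "")) {
    stop("all configuration overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(nm, names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in nm) {
    v <- overrides[[k]]
    if (is.list(v)) v <- unlist(v, use.names = FALSE)
    cfg[[k]] <- v
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$movement_threshold_g > 0,
    cfg$epoch_s > 0,
    cfg$left_lateral_deg > 0,
    cfg$left_lateral_deg < cfg$right_lateral_deg,
    cfg$right_lateral_deg < 180,
    cfg$supine_deg > 0, cfg$supine_deg < 90,
    length(cfg$move_band_hz) == 2L, cfg$move_band_hz[1] < cfg$move_band_hz[2],
    cfg$lfhf_convention %in% c("power", "amplitude"),
    cfg$sinus_frac_basis %in% c("beats", "time"),
    cfg$ahi_severity_cutoff > 0
  )
  invisible(cfg)
}

#' Read analysis parameters from a YAML file
#'
#' Keys not present in the file keep their defaults; keys not known to
#' [phrv_config()] raise an error so that typos do not silently fall back to
#' defaults. An empty file (or a file containing only comments) yields the
#' full default parameter set.
#'
#' @param path Path to a YAML key/value file.
#' @return A `"phrv_config"` parameter list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain key/value pairs", call. = FALSE)
  do.call(phrv_config, raw)
}

#' @export
print.phrv_config <- function(x, ...) {
  cat("<posturehrv configuration>\n")
  for (k in names(x)) {
    cat(sprintf("  %-24s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}

#' Log a pipeline stage with its effective parameters
#'
#' One line per stage so that runs are auditable: which stage ran, with which
#' parameter values. Silent unless `verbose` is TRUE.
#'
#' @param stage Stage name.
#' @param params Named list of the parameters in effect for the stage.
#' @param verbose Emit the line via [message()]?
#' @return The formatted log line, invisibly.
#' @export
log_stage <- function(stage, params = list(), verbose = FALSE) {
  kv <- if (length(params) > 0L) {
    paste(vapply(names(params), function(k) {
      paste0(k, "=", paste(format(params[[k]]), collapse = "/"))
    }, character(1)), collapse = " ")
  } else ""
  line <- trimws(paste0("[", stage, "] ", kv))
  if (isTRUE(verbose)) message(line)
  invisible(line)
}
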