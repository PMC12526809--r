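#' Flag movement epochs from band-passed acceleration
#'
#' Each axis is passed through a 2--3 Hz band-pass filter to isolate body
#' movement; the composite magnitude is the root sum of squares of the three
#' filtered axes. A 30 s epoch is flagged as movement when the maximum
#' composite magnitude within it reaches `movement_threshold_g` (20 mG by
#' default). A trailing partial epoch is dropped.
#'
#' @param accel An [accel_series()].
#' @param config A [phrv_config()].
#' @return Logical vector, one element per complete 30 s epoch.
#' @export
movement_flags <- function(accel, config = phrv_config()) {
  stopifnot(inherits(accel, "accel_series"))
  n <- length(accel$x)
  if (n / accel$fs < config$epoch_s) {
    stop("recording shorter than one epoch", call. = FALSE)
  }
  xf <- butter_bandpass(accel$x, accel$fs, config$move_band_hz)
  yf <- butter_bandpass(accel$y, accel$fs, config$move_band_hz)
  zf <- butter_bandpass(accel$z, accel$fs, config$move_band_hz)
  mag <- sqrt(xf^2 + yf^2 + zf^2)
  per_epoch <- epoch_split(mag, accel$fs, config$epoch_s)
  vapply(per_epoch, max, numeric(1)) >= config$movement_threshold_g
}

# number of complete epochs in n samples; an epoch short by less than one
# sample still counts (fs * epoch_s need not be an integer, e.g. 937.5
# samples at 31.25 Hz)
n_epochs <- function(n, fs, epoch_s) {
  spe <- fs * epoch_s
  k <- floor((n + 1) / spe)
  while (k > 0L && round(k * spe) > n) k <- k - 1L
  as.integer(k)
}

# split a per-sample vector into complete epochs via time-based boundaries
epoch_split <- function(v, fs, epoch_s) {
  spe <- fs * epoch_s
  n_ep <- n_epochs(length(v), fs, epoch_s)
  if (n_ep < 1L) return(list())
  cuts <- round((0:n_ep) * spe)
  lapply(seq_len(n_ep), function(k) v[seq(cuts[k] + 1L, cuts[k + 1L])])
}

#' Extract the gravitational component of an acceleration series
#'
#' Low-pass filters each axis at `gravity_corner_hz` (0.1 Hz) with a
#' zero-phase filter so the gravity estimate is not time-shifted relative to
#' the epoch grid.
#'
#' @inheritParams movement_flags
#' @return A list with numeric vectors `x`, `y`, `z` (per-sample gravity
#'   estimate, g).
#' @export
gravity <- function(accel, config = phrv_config()) {
  stopifnot(inherits(accel, "accel_series"))
  if (length(accel$x) / accel$fs < config$epoch_s) {
    stop("recording shorter than one epoch", call. = FALSE)
  }
  list(
    x = butter_lowpass(accel$x, accel$fs, config$gravity_corner_hz),
    y = butter_lowpass(accel$y, accel$fs, config$gravity_corner_hz),
    z = butter_lowpass(accel$z, accel$fs, config$gravity_corner_hz)
  )
}

#' Classify posture from a gravity vector
#'
#' Applies the angle rules to the gravity (reaction) vector, which points
#' skyward at rest. With theta_A the angle between the gravity vector and
#' body axis A: the posture is lying when theta_X is within
#' `lying_center_deg +/- lying_halfwidth_deg` (84 +/- 36, i.e. 48--120
#' degrees, boundaries inclusive). Lying samples are left lateral when
#' theta_Y < 65 degrees, right lateral when theta_Y > 111 degrees, otherwise
#' supine when theta_Z < 60 degrees and prone otherwise. Samples outside the
#' lying window are `non_lying`.
#'
#' Sign convention: X positive toward the head, Y toward the subject's
#' right, Z toward the front (out of the chest). Lying on the back puts the
#' sky along +Z (supine); lying on the left side puts it along +Y (left
#' lateral).
#'
#' @param g A length-3 numeric vector `(gx, gy, gz)` or an n x 3 matrix of
#'   gravity vectors in g. Need not be normalised, but must be non-zero.
#' @param config A [phrv_config()].
#' @return Character vector of labels in
#'   `{supine, right_lateral, left_lateral, prone, non_lying}`.
#' @export
#' @examples
#' sample_posture(c(0, 0, 1))   # back-lying: supine
#' sample_posture(c(0, 1, 0))   # left-side-lying: left_lateral
#' sample_posture(c(1, 0, 0))   # upright: non_lying
sample_posture <- function(g, config = phrv_config()) {
  if (is.null(dim(g))) {
    stopifnot(length(g) == 3L)
    g <- matrix(g, nrow = 1L)
  }
  stopifnot(ncol(g) == 3L)
  nrm <- sqrt(rowSums(g^2))
  if (any(nrm == 0 | !is.finite(nrm))) {
    stop("gravity vector must be non-zero and finite", call. = FALSE)
  }
  ang <- function(comp) acos(pmin(1, pmax(-1, comp / nrm))) * 180 / pi
  th_x <- ang(g[, 1L]); th_y <- ang(g[, 2L]); th_z <- ang(g[, 3L])
  lo <- config$lying_center_deg - config$lying_halfwidth_deg
  hi <- config$lying_center_deg + config$lying_halfwidth_deg
  lying <- th_x >= lo & th_x <= hi
  out <- rep("non_lying", nrow(g))
  out[lying & th_y < config$left_lateral_deg] <- "left_lateral"
  out[lying & th_y > config$right_lateral_deg] <- "right_lateral"
  rest <- lying & out == "non_lying"
  out[rest & th_z < config$supine_deg] <- "supine"
  out[rest & th_z >= config$supine_deg] <- "prone"
  out
}

#' Label 30 s epochs from per-sample postures and movement flags
#'
#' Movement epochs keep the label `movement` and are never posture-labelled.
#' Among non-movement epochs, an epoch is labelled with the posture that
#' accounts for more than `majority_frac` (default 50%) of its samples;
#' when no single posture exceeds that share the epoch is a `transition`.
#' An epoch whose majority label is `non_lying` is labelled `non_lying`.
#'
#' @param sample_labels Character vector of per-sample posture labels (from
#'   [sample_posture()]).
#' @param movement Logical per-epoch movement flags (from
#'   [movement_flags()]); must cover the same epochs.
#' @param fs Sampling rate of `sample_labels` in Hz.
#' @param start_time Time of the first sample, seconds since midnight.
#' @param config A [phrv_config()].
#' @return A data.frame with columns `epoch_index` (0-based), `t_start`
#'   (seconds since midnight) and `label`.
#' @export
label_epochs <- function(sample_labels, movement, fs,
                         start_time = 0, config = phrv_config()) {
  per_epoch <- epoch_split(sample_labels, fs, config$epoch_s)
  n_ep <- length(per_epoch)
  if (length(movement) != n_ep) {
    stop("movement flags and sample labels cover different epoch counts",
         call. = FALSE)
  }
  lab <- character(n_ep)
  for (k in seq_len(n_ep)) {
    if (movement[k]) {
      lab[k] <- "movement"
      next
    }
    tab <- table(per_epoch[[k]])
    share <- max(tab) / length(per_epoch[[k]])
    if (share <= config$majority_frac) {
      lab[k] <- "transition"
    } else {
      modal <- names(tab)[which.max(tab)]
      lab[k] <- modal  # non_lying majority stays non_lying
    }
  }
  data.frame(
    epoch_index = seq_len(n_ep) - 1L,
    t_start = start_time + (seq_len(n_ep) - 1L) * config$epoch_s,
    label = lab,
    stringsAsFactors = FALSE
  )
}

lying_postures <- c("supine", "right_lateral", "left_lateral", "prone")

#' Posture percentages over posture-labelled epochs
#'
#' The share of each lying posture among the posture-labelled epochs only:
#' movement, transition and non_lying epochs are excluded from both the
#' numerator and the denominator, so the four percentages sum to 100.
#'
#' @param labels Character vector of epoch labels (or the data.frame from
#'   [label_epochs()]).
#' @return Named numeric vector of percentages for supine, right_lateral,
#'   left_lateral, prone; all `NA` (with a warning) when no epoch carries a
#'   posture label.
#' @export
posture_percentages <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  keep <- labels[labels %in% lying_postures]
  out <- stats::setNames(rep(NA_real_, 4L), lying_postures)
  if (length(keep) == 0L) {
    warning("no posture-labelled epochs; percentages undefined")
    return(out)
  }
  for (p in lying_postures) out[p] <- 100 * sum(keep == p) / length(keep)
  out
}

#' Per-posture recall and precision of predicted epoch labels
#'
#' For each of the four lying postures p: recall = TP / (TP + FN) over
#' epochs whose true label is p, and precision = TP / (TP + FP) over epochs
#' predicted as p. Predicted labels outside the four postures (movement,
#' transition, non_lying) count against recall of the true class but never
#' contribute to any precision. Cells with an empty denominator are `NA`.
#'
#' @param truth,predicted Equal-length character vectors of epoch labels.
#' @return A data.frame with columns `posture`, `recall`, `precision`,
#'   `n_true`.
#' @export
validate_classifier <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  vocab <- c(lying_postures, "movement", "transition", "non_lying")
  bad <- setdiff(unique(c(truth, predicted)), vocab)
  if (length(bad) > 0L) {
    stop("label(s) outside vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  res <- data.frame(posture = lying_postures, recall = NA_real_,
                    precision = NA_real_, n_true = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(lying_postures)) {
    p <- lying_postures[i]
    tp <- sum(truth == p & predicted == p)
    fn <- sum(truth == p & predicted != p)
    fp <- sum(truth != p & predicted == p)
    res$n_true[i] <- tp + fn
    if (tp + fn > 0L) res$recall[i] <- tp / (tp + fn)
    if (tp + fp > 0L) res$precision[i] <- tp / (tp + fp)
  }
  res
}

#' Run the full posture classifier on an acceleration series
#'
#' Convenience wrapper chaining [movement_flags()], [gravity()],
#' [sample_posture()] and [label_epochs()]. Also reports, per epoch, the
#' mean angle of the gravity vector with each body axis for audit.
#'
#' @inheritParams movement_flags
#' @param verbose Log each stage with its effective parameters.
#' @return A data.frame with columns `epoch_index`, `t_start`, `label`,
#'   `movement`, `theta_x`, `theta_y`, `theta_z`.
#' @export
classify_posture <- function(accel, config = phrv_config(), verbose = FALSE) {
  log_stage("movement", config[c("move_band_hz", "movement_threshold_g")],
            verbose)
  mov <- movement_flags(accel, config)
  log_stage("gravity", config["gravity_corner_hz"], verbose)
  g <- gravity(accel, config)
  gm <- cbind(g$x, g$y, g$z)
  log_stage("posture", config[c("lying_center_deg", "lying_halfwidth_deg",
                                "left_lateral_deg", "right_lateral_deg",
                                "supine_deg", "majority_frac")], verbose)
  labs <- sample_posture(gm, config)
  ep <- label_epochs(labs, mov, accel$fs, accel$start_time, config)
  ep$movement <- mov
  nrm <- sqrt(rowSums(gm^2))
  for (ax in 1:3) {
    th <- acos(pmin(1, pmax(-1, gm[, ax] / nrm))) * 180 / pi
    mean_ep <- vapply(epoch_split(th, accel$fs, config$epoch_s), mean,
                      numeric(1))
    ep[[c("theta_x", "theta_y", "theta_z")[ax]]] <- mean_ep
  }
  ep
}
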