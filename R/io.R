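#' Triaxial acceleration series
#'
#' Container for chest-worn accelerometer data. The device axes are assumed
#' to be aligned with the body: X along the head--foot axis (positive toward
#' the head), Y along the left--right axis (positive toward the subject's
#' right), Z along the front--back axis (positive toward the front, out of
#' the chest). Values are in g; at rest the low-passed signal is the gravity
#' reaction vector, which points skyward with magnitude 1 g.
#'
#' @param x,y,z Numeric vectors of equal length, acceleration in g.
#' @param fs Sampling rate in Hz (device default 31.25).
#' @param start_time Time of the first sample in seconds since midnight;
#'   recordings crossing midnight continue past 86400.
#' @return An object of class `"accel_series"`.
#' @export
accel_series <- function(x, y, z, fs = 31.25, start_time = 0) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  if (length(x) != length(y) || length(x) != length(z)) {
    stop("x, y, z must have equal length", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || anyNA(z) ||
      any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z))) {
    stop("acceleration values must be finite", call. = FALSE)
  }
  structure(
    list(x = x, y = y, z = z, fs = fs, start_time = as.numeric(start_time)),
    class = "accel_series"
  )
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf(
    "<accel_series> %d samples @ %.4g Hz (%.1f min), start %.1f s\n",
    length(x$x), x$fs, length(x$x) / x$fs / 60, x$start_time
  ))
  invisible(x)
}

#' @export
length.accel_series <- function(x) length(x$x)

#' Sample timestamps of an acceleration series
#' @param accel An [accel_series()].
#' @return Numeric vector of times in seconds since midnight.
#' @export
accel_times <- function(accel) {
  accel$start_time + (seq_along(accel$x) - 1) / accel$fs
}

#' Beat series with rhythm annotations
#'
#' One row per detected QRS complex: its time, the RR interval ending at it,
#' and a rhythm label. Labels: `N` sinus, `V` ventricular ectopic, `S`
#' supraventricular ectopic, `A` artifact. The first beat's RR interval is
#' undefined (`NA`). Only intervals flanked by two `N` beats (NN intervals)
#' enter HRV analysis.
#'
#' @param beat_time Strictly increasing beat times, seconds since midnight.
#' @param rr_ms RR interval ending at each beat, ms; `NA` for the first beat.
#' @param label Per-beat rhythm label in `{N, V, S, A}` (default all `N`).
#' @return An object of class `"beat_series"`.
#' @export
beat_series <- function(beat_time, rr_ms = NULL, label = NULL) {
  beat_time <- as.numeric(beat_time)
  n <- length(beat_time)
  if (n > 1L && any(diff(beat_time) <= 0)) {
    stop("beat_time must be strictly increasing", call. = FALSE)
  }
  if (is.null(rr_ms)) {
    rr_ms <- c(NA_real_, diff(beat_time) * 1000)
  }
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) != n) stop("rr_ms length mismatch", call. = FALSE)
  if (any(rr_ms[-1L] <= 0, na.rm = TRUE)) {
    stop("rr_ms must be positive where defined", call. = FALSE)
  }
  if (is.null(label)) label <- rep("N", n)
  label <- as.character(label)
  if (length(label) != n) stop("label length mismatch", call. = FALSE)
  bad <- setdiff(unique(label), c("N", "V", "S", "A"))
  if (length(bad) > 0L) {
    stop("unknown beat label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(beat_time = beat_time, rr_ms = rr_ms, label = label),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  n <- length(x$beat_time)
  cat(sprintf(
    "<beat_series> %d beats (%.1f min), %.1f%% sinus\n",
    n, if (n > 1) diff(range(x$beat_time)) / 60 else 0,
    100 * mean(x$label == "N")
  ))
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$beat_time)

#' Read and write acceleration CSV files
#'
#' The on-disk format is a plain CSV with header `t,x,y,z`: time in seconds
#' since midnight and the three axis components in g. The sampling rate is
#' inferred from the median time step and checked against `fs` (within 1%)
#' when one is declared.
#'
#' @param path File path.
#' @param fs Declared sampling rate, or `NULL` to accept the inferred one.
#' @return `read_accel()` returns an [accel_series()]; `write_accel()`
#'   returns `path` invisibly.
#' @export
read_accel <- function(path, fs = NULL) {
  d <- utils::read.csv(path)
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(d))) {
    stop("accel file must have columns t,x,y,z", call. = FALSE)
  }
  if (nrow(d) < 2L) stop("accel file needs at least 2 samples", call. = FALSE)
  dt <- diff(d$t)
  if (any(dt <= 0)) stop("time column must be strictly increasing", call. = FALSE)
  fs_inf <- 1 / stats::median(dt)
  if (!is.null(fs) && abs(fs_inf - fs) / fs > 0.01) {
    stop(sprintf("inferred rate %.4g Hz does not match declared %.4g Hz",
                 fs_inf, fs), call. = FALSE)
  }
  accel_series(d$x, d$y, d$z, fs = if (is.null(fs)) fs_inf else fs,
               start_time = d$t[1])
}

#' @rdname read_accel
#' @param accel An [accel_series()] to write.
#' @export
write_accel <- function(accel, path) {
  stopifnot(inherits(accel, "accel_series"))
  num <- function(v) sprintf("%.17g", v)
  d <- data.frame(t = num(accel_times(accel)), x = num(accel$x),
                  y = num(accel$y), z = num(accel$z))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write beat-annotation CSV files
#'
#' Plain CSV with header `beat_time,rr_ms,label`. Labels outside
#' `{N, V, S, A}` and non-positive RR intervals are format errors.
#'
#' @param path File path.
#' @return `read_beats()` returns a [beat_series()]; `write_beats()` returns
#'   `path` invisibly.
#' @export
read_beats <- function(path) {
  d <- utils::read.csv(path, colClasses = c(label = "character"))
  need <- c("beat_time", "rr_ms", "label")
  if (!all(need %in% names(d))) {
    stop("beats file must have columns beat_time,rr_ms,label", call. = FALSE)
  }
  beat_series(d$beat_time, d$rr_ms, d$label)
}

#' @rdname read_beats
#' @param beats A [beat_series()] to write.
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  d <- data.frame(beat_time = sprintf("%.17g", beats$beat_time),
                  rr_ms = ifelse(is.na(beats$rr_ms), "NA",
                                 sprintf("%.17g", beats$rr_ms)),
                  label = beats$label)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
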