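# Zero-phase Butterworth filtering with edge padding.
#
# signal::filtfilt() starts both passes from zero state, which leaves a long
# transient when the corner frequency is far below the sampling rate (the
# 0.1 Hz gravity filter at 31.25 Hz would corrupt the first epochs of every
# recording). Odd-reflection padding about the end samples fixes that and
# leaves constant inputs exactly unchanged.

zero_phase <- function(x, filt, fs, corner_hz) {
  n <- length(x)
  npad <- min(n - 1L, ceiling(3 * fs / corner_hz))
  if (npad < 1L) return(signal::filtfilt(filt, x))
  front <- 2 * x[1L] - x[seq(npad + 1L, 2L)]
  back  <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  y <- signal::filtfilt(filt, c(front, x, back))
  y[seq(npad + 1L, npad + n)]
}

# Second-order Butterworth run forward-backward: fourth-order zero-phase
# magnitude response at the stated corner(s).
butter_lowpass <- function(x, fs, corner_hz) {
  filt <- signal::butter(2, corner_hz / (fs / 2), type = "low")
  zero_phase(x, filt, fs, corner_hz)
}

butter_bandpass <- function(x, fs, band_hz) {
  filt <- signal::butter(2, band_hz / (fs / 2), type = "pass")
  zero_phase(x, filt, fs, band_hz[1])
}
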