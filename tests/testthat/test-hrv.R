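test_that("NN extraction keeps only intervals flanked by sinus beats", {
  b <- beat_series(1:6, label = c("N", "N", "V", "N", "N", "N"))
  nn <- extract_nn(b)
  # intervals ending at beats 2, 5, 6 survive; those touching the V drop out
  expect_equal(nn$time, c(2, 5, 6))
  b2 <- beat_series(1:6, label = rep(c("N", "V"), 3))
  expect_warning(nn2 <- extract_nn(b2), "no NN")
  expect_length(nn2$time, 0)
  b3 <- beat_series(1:10)
  expect_length(extract_nn(b3)$time, 9)
})

test_that("per-epoch HR and SDRR match closed forms", {
  # constant 1000 ms
  nn <- extract_nn(beat_series(seq(0, 30, by = 1)))
  ep <- make_epochs(1)
  hs <- epoch_hr_sdrr(nn, ep)
  expect_equal(hs$hr_bpm, 60)
  expect_equal(hs$sdrr_ms, 0)
  # alternating 800/1200 ms, 30 intervals: HR 60, SDRR 200*sqrt(30/29);
  # the train sits strictly inside the second epoch of a 2-epoch grid
  bt <- 29.95 + cumsum(c(0, rep(c(0.8, 1.2), 15)))
  nn2 <- extract_nn(beat_series(bt))
  hs2 <- epoch_hr_sdrr(nn2, make_epochs(2))
  expect_equal(hs2$n_nn[2], 30L)
  expect_equal(hs2$hr_bpm[2], 60, tolerance = 1e-12)
  expect_equal(hs2$sdrr_ms[2], 200 * sqrt(30 / 29), tolerance = 1e-9)
  # fewer than 10 intervals -> NA
  nn3 <- extract_nn(beat_series(seq(0, 5, by = 1)))
  hs3 <- epoch_hr_sdrr(nn3, make_epochs(1))
  expect_true(is.na(hs3$hr_bpm) && is.na(hs3$sdrr_ms))
  # brute-force recomputation agrees on a random series
  set.seed(4)
  gb <- gen_beats(rr_model(mean_rr_ms = 900,
                           hf = list(amp_ms = 40, freq_hz = 0.25,
                                     jitter_sd_hz = 0)), 700)
  nn4 <- extract_nn(gb$beats)
  ep4 <- make_epochs(20)
  hs4 <- epoch_hr_sdrr(nn4, ep4)
  for (k in c(3, 11, 17)) {
    sel <- nn4$time >= ep4$t_start[k] & nn4$time < ep4$t_start[k] + 30
    expect_equal(hs4$hr_bpm[k], 60000 / mean(nn4$rr_ms[sel]))
    expect_equal(hs4$sdrr_ms[k], stats::sd(nn4$rr_ms[sel]))
  }
})

test_that("2 Hz spline resampling reproduces smooth tachograms", {
  # constant series stays constant
  nn <- extract_nn(beat_series(seq(0, 120, by = 1)))
  rs <- resample_2hz(nn)
  expect_true(all(abs(rs$rr_ms - 1000) < 1e-9))
  expect_equal(diff(rs$t), rep(0.5, length(rs$t) - 1), tolerance = 1e-12)
  # sinusoidal tachogram sampled at ~1 Hz recovered within 2 ms
  f <- 0.25
  bt <- seq(0, 300, by = 0.97)
  nn2 <- make_nn(bt, 1000 + 50 * sin(2 * pi * f * bt))
  rs2 <- resample_2hz(nn2)
  ref <- 1000 + 50 * sin(2 * pi * f * rs2$t)
  inner <- rs2$t > 5 & rs2$t < 295
  expect_lt(max(abs(rs2$rr_ms[inner] - ref[inner])), 2)
  # long annotation gaps are masked
  bt3 <- c(seq(0, 60, 1), seq(75, 130, 1))
  rs3 <- resample_2hz(extract_nn(beat_series(bt3)))
  gap <- rs3$t > 61 & rs3$t < 74
  expect_true(all(!rs3$valid[gap]))
  expect_true(all(rs3$valid[rs3$t < 59]))
  expect_error(resample_2hz(extract_nn(beat_series(c(0, 1)))), "at least 4")
})

test_that("complex demodulation recovers single tones and separates bands", {
  tt <- seq(0, 1023.5, by = 0.5)
  # pure HF tone: amplitude and frequency recovered away from edges
  x <- make_resampled(1000 + 50 * sin(2 * pi * 0.25 * tt))
  d <- complex_demodulate(x, "HF")
  core <- which(tt > 100 & tt < 920)
  expect_lt(max(abs(d$amp_ms[core] - 50)) / 50, 0.05)
  expect_lt(max(abs(d$inst_freq_hz[core] - 0.25)), 0.005)
  # zero signal: amp 0, frequency reported at the band centre
  d0 <- complex_demodulate(make_resampled(rep(1000, 2048)), "HF")
  expect_true(all(d0$amp_ms < 1e-9))
  expect_true(all(d0$inst_freq_hz == d0$f0))
  # two tones: each band tracks its own, cross-talk < 5%
  x2 <- make_resampled(1000 + 30 * sin(2 * pi * 0.10 * tt) +
                         50 * sin(2 * pi * 0.25 * tt))
  dl <- complex_demodulate(x2, "LF")
  dh <- complex_demodulate(x2, "HF")
  expect_lt(abs(mean(dl$amp_ms[core]) - 30) / 30, 0.05)
  expect_lt(abs(mean(dh$amp_ms[core]) - 50) / 50, 0.05)
  expect_error(complex_demodulate(x2, "XF"), "band")
})

test_that("tone recovery holds property-wise across band interiors", {
  set.seed(6)
  cfg <- phrv_config()
  bands <- list(VLF = cfg$vlf_band_hz, LF = cfg$lf_band_hz,
                HF = cfg$hf_band_hz)
  tt <- seq(0, 4095.5, by = 0.5)
  for (i in 1:15) {
    bn <- names(bands)[1 + (i %% 3)]
    e <- bands[[bn]]
    bw <- diff(e)
    f <- runif(1, e[1] + 0.2 * bw, e[2] - 0.2 * bw)
    a <- runif(1, 10, 100)
    x <- make_resampled(1000 + a * sin(2 * pi * f * tt))
    d <- complex_demodulate(x, bn)
    # settle time scales with the band's filter corner
    edge <- ceiling(3 / (bw / 2))
    core <- which(tt > edge & tt < max(tt) - edge)
    expect_lt(abs(mean(d$amp_ms[core]) - a) / a, 0.05)
    expect_lt(abs(mean(d$inst_freq_hz[core]) - f), 0.005)
  }
})

test_that("band amplitudes ignore a DC shift of the tachogram", {
  tt <- seq(0, 1023.5, by = 0.5)
  base <- 900 + 40 * sin(2 * pi * 0.25 * tt) + 25 * sin(2 * pi * 0.1 * tt)
  for (bn in c("VLF", "LF", "HF")) {
    d1 <- complex_demodulate(make_resampled(base), bn)
    d2 <- complex_demodulate(make_resampled(base + 250), bn)
    expect_equal(d1$amp_ms, d2$amp_ms, tolerance = 1e-9)
  }
})

test_that("epoch band statistics average amplitudes and form LF/HF", {
  tt <- seq(0, 1023.5, by = 0.5)
  x <- make_resampled(1000 + 30 * sin(2 * pi * 0.10 * tt) +
                        30 * sin(2 * pi * 0.25 * tt))
  demods <- list(vlf = complex_demodulate(x, "VLF"),
                 lf = complex_demodulate(x, "LF"),
                 hf = complex_demodulate(x, "HF"))
  ep <- make_epochs(34)
  st <- epoch_band_stats(demods, ep)
  mid <- 10:20  # epochs away from filter edges
  # equal amplitudes give LF/HF 1 under the power convention
  expect_true(all(abs(st$lf_hf[mid] - 1) < 0.15))
  expect_true(all(abs(st$hf_freq_hz[mid] - 0.25) < 0.005))
  # doubling LF amplitude gives LF/HF 4 (squared-ratio convention) ...
  x2 <- make_resampled(1000 + 60 * sin(2 * pi * 0.10 * tt) +
                         30 * sin(2 * pi * 0.25 * tt))
  demods2 <- list(vlf = complex_demodulate(x2, "VLF"),
                  lf = complex_demodulate(x2, "LF"),
                  hf = complex_demodulate(x2, "HF"))
  st2 <- epoch_band_stats(demods2, ep)
  expect_true(all(abs(st2$lf_hf[mid] - 4) < 0.5))
  # ... and 2 under the amplitude convention
  st3 <- epoch_band_stats(demods2, ep,
                          phrv_config(lfhf_convention = "amplitude"))
  expect_true(all(abs(st3$lf_hf[mid] - 2) < 0.2))
})

test_that("Hsi is high for stable tones, near the flat-spectrum level for noise", {
  ep <- make_epochs(34)
  tt <- seq(0, 1023.5, by = 0.5)
  set.seed(8)
  x <- make_resampled(1000 + 50 * sin(2 * pi * 0.25 * tt) +
                        rnorm(length(tt), 0, 1))
  h <- hsi(x, ep)
  expect_gte(min(h$hsi_pct, na.rm = TRUE), 95)
  expect_true(all(h$hsi_pct <= 100 & h$hsi_pct >= 0, na.rm = TRUE))
  # epochs whose 256 s window leaves the record are NA
  expect_true(is.na(h$hsi_pct[1]) && is.na(h$hsi_pct[34]))
  # white noise: expected concentration ~ (2W+1)/64 of the HF band power,
  # slightly above because the peak bin is selected as the maximum
  vals <- replicate(12, {
    xn <- make_resampled(1000 + rnorm(length(tt), 0, 20))
    mean(hsi(xn, ep)$hsi_pct, na.rm = TRUE)
  })
  expect_gt(mean(vals), 10)
  expect_lt(mean(vals), 30)
})

test_that("Hsi falls monotonically with respiratory-frequency jitter", {
  jits <- c(0, 0.0075, 0.015, 0.0225, 0.03)
  set.seed(9)
  ep <- make_epochs(30)
  med <- sapply(jits, function(j) {
    mean(replicate(4, {
      m <- rr_model(hf = list(amp_ms = 40, freq_hz = 0.25, jitter_sd_hz = j))
      gb <- gen_beats(m, 930)
      mean(hsi(resample_2hz(extract_nn(gb$beats)), ep)$hsi_pct, na.rm = TRUE)
    }))
  })
  rho <- stats::cor(jits, med, method = "spearman")
  expect_lt(rho, 0)
  expect_lt(med[5], med[1])
})
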