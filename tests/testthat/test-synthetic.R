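test_that("gen_accel honours schedule, truth labels and determinism", {
  sched <- posture_schedule(data.frame(
    start_s = 0, duration_s = 120, posture = "supine"))
  ga <- gen_accel(sched, noise_sd_g = 0, orientation_jitter_deg = 0, seed = 1)
  # zero noise, zero jitter: every sample is the supine canonical vector
  expect_true(all(abs(ga$accel$x) < 1e-12))
  expect_true(all(abs(ga$accel$y) < 1e-12))
  expect_true(all(abs(ga$accel$z - 1) < 1e-12))
  expect_equal(ga$truth$label, rep("supine", 4))

  # one 60 s burst overlapping two aligned epochs
  sched2 <- posture_schedule(
    data.frame(start_s = 0, duration_s = 300, posture = "prone"),
    movement_bursts = data.frame(start_s = 60, duration_s = 60))
  ga2 <- gen_accel(sched2, seed = 2)
  expect_equal(sum(ga2$truth$label == "movement"), 2L)
  ep <- classify_posture(ga2$accel)
  expect_identical(ep$label, ga2$truth$label)
  # a straddling burst marks three epochs
  sched3 <- posture_schedule(
    data.frame(start_s = 0, duration_s = 300, posture = "prone"),
    movement_bursts = data.frame(start_s = 75, duration_s = 60))
  ga3 <- gen_accel(sched3, seed = 2)
  expect_equal(sum(ga3$truth$label == "movement"), 3L)

  # determinism under a fixed seed
  gb1 <- gen_accel(sched2, seed = 7)
  gb2 <- gen_accel(sched2, seed = 7)
  expect_identical(gb1$accel$x, gb2$accel$x)
  expect_identical(gb1$truth, gb2$truth)

  expect_error(gen_accel(sched, orientation_jitter_deg = 30), "jitter")
  expect_error(posture_schedule(data.frame(
    start_s = c(0, 100), duration_s = c(60, 60),
    posture = c("supine", "prone"))), "contiguous")
})

test_that("gen_beats produces the prescribed band structure", {
  # silent model: constant RR train, all sinus
  gb <- gen_beats(rr_model(mean_rr_ms = 1000), 700, seed = 1)
  expect_true(all(abs(gb$beats$rr_ms[-1] - 1000) < 1e-9))
  expect_true(all(gb$beats$label == "N"))
  expect_true(all(diff(gb$beats$beat_time) > 0))

  # single HF tone at 0.25 Hz dominates the spectrum of the resampled series
  m <- rr_model(hf = list(amp_ms = 50, freq_hz = 0.25, jitter_sd_hz = 0))
  gb2 <- gen_beats(m, 1024, seed = 2)
  rs <- resample_2hz(extract_nn(gb2$beats))
  x <- rs$rr_ms - mean(rs$rr_ms)
  pw <- Mod(stats::fft(x))^2
  fr <- (seq_along(x) - 1) * rs$fs / length(x)
  half <- seq(2, floor(length(x) / 2))
  expect_equal(fr[half][which.max(pw[half])], 0.25, tolerance = 0.005)

  # dip trains are recorded in the truth
  m3 <- rr_model(mean_rr_ms = 1000,
                 cvhr = list(dip_depth_ms = 150, dip_width_s = 30,
                             inter_dip_s = 60, train_starts = 120,
                             dips_per_train = 10))
  gb3 <- gen_beats(m3, 900, seed = 3)
  expect_equal(gb3$truth$dip_times, 120 + (0:9) * 60)
  expect_error(rr_model(mean_rr_ms = 100,
                        cvhr = list(dip_depth_ms = 150, dip_width_s = 30,
                                    inter_dip_s = 60, train_starts = 120)),
               "depth")

  # ectopic beats carry V labels and shortened intervals
  gb4 <- gen_beats(rr_model(mean_rr_ms = 1000, ectopic_prob = 0.05), 900,
                   seed = 4)
  expect_gt(sum(gb4$beats$label == "V"), 0)
  v <- which(gb4$beats$label == "V")
  v <- v[v > 1 & v < length(gb4$beats$rr_ms)]
  expect_true(all(abs(gb4$beats$rr_ms[v + 1] - 700) < 1e-6))
})

test_that("beat times stay strictly increasing across random models", {
  set.seed(11)
  for (i in 1:5) {
    m <- rr_model(mean_rr_ms = runif(1, 600, 1200),
                  vlf = list(amp_ms = runif(1, 0, 60), freq_hz = 0.02),
                  lf = list(amp_ms = runif(1, 0, 50), freq_hz = 0.1),
                  hf = list(amp_ms = runif(1, 0, 50), freq_hz = 0.3,
                            jitter_sd_hz = 0.02),
                  ectopic_prob = 0.05)
    gb <- gen_beats(m, 700)
    expect_true(all(diff(gb$beats$beat_time) > 0))
  }
})

test_that("gen_cohort injects recoverable posture effects", {
  co <- gen_cohort(8, age_bins = 50,
                   index_effects = list(hr_offset_bpm = c(left_lateral = -3)),
                   duration_h = 6, seed = 21)
  expect_length(co$subjects, 8)
  expect_equal(nrow(co$truth), 8)
  expect_error(gen_cohort(3), "at least 4")
  ca <- analyze_cohort(co$subjects, compute = "time")
  w <- stats::reshape(ca$long[, c("subject_id", "posture", "hr_bpm")],
                      idvar = "subject_id", timevar = "posture",
                      direction = "wide")
  d <- w$hr_bpm.left_lateral - w$hr_bpm.right_lateral
  expect_lt(abs(mean(d, na.rm = TRUE) - (-3)), 0.5)
  # determinism
  co2 <- gen_cohort(4, seed = 9)
  co3 <- gen_cohort(4, seed = 9)
  expect_identical(co2$truth, co3$truth)
  expect_identical(co2$subjects[[2]]$beats$beat_time,
                   co3$subjects[[2]]$beats$beat_time)
})
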