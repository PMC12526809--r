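test_that("movement detection responds to 2-3 Hz content only", {
  fs <- 31.25
  t <- (0:(fs * 90 - 1)) / fs
  # silence
  a0 <- accel_series(rep(0, length(t)), rep(0, length(t)), rep(1, length(t)),
                     fs = fs)
  expect_false(any(movement_flags(a0)))
  # a 2.5 Hz, 0.03 g oscillation confined to the second epoch
  burst <- 0.03 * sin(2 * pi * 2.5 * t) * (t >= 30 & t < 60)
  a1 <- accel_series(rep(0, length(t)), burst, rep(1, length(t)), fs = fs)
  expect_identical(movement_flags(a1), c(FALSE, TRUE, FALSE))
  # a slow 0.05 Hz full-gravity tilt is not movement
  a2 <- accel_series(sin(2 * pi * 0.05 * t), rep(0, length(t)),
                     cos(2 * pi * 0.05 * t), fs = fs)
  expect_false(any(movement_flags(a2)))
})

test_that("gravity extraction has unit DC gain and attenuates 1 Hz ripple", {
  fs <- 31.25
  t <- (0:(fs * 120 - 1)) / fs
  a <- accel_series(rep(0, length(t)), rep(0, length(t)), rep(1, length(t)),
                    fs = fs)
  g <- gravity(a)
  expect_lt(max(abs(g$z - 1)), 1e-4)
  expect_lt(max(abs(g$x)), 1e-9)
  # 1 Hz ripple attenuated by >= 20 dB
  a2 <- accel_series(0.2 * sin(2 * pi * 1 * t), rep(0, length(t)),
                     rep(1, length(t)), fs = fs)
  g2 <- gravity(a2)
  core <- seq(round(30 * fs), round(90 * fs))
  expect_lt(max(abs(g2$x[core])), 0.2 / 10)
  # norm stays ~1 g during static lying with noise
  set.seed(1)
  a3 <- accel_series(rnorm(length(t), 0, 0.005), rnorm(length(t), 1, 0.005),
                     rnorm(length(t), 0, 0.005), fs = fs)
  g3 <- gravity(a3)
  nrm <- sqrt(g3$x^2 + g3$y^2 + g3$z^2)
  expect_lt(max(abs(nrm - 1)), 0.02)
})

test_that("sample_posture matches the analytic examples", {
  expect_equal(sample_posture(c(0, 0, 1)), "supine")
  expect_equal(sample_posture(c(0, 0, -1)), "prone")
  expect_equal(sample_posture(c(0, 1, 0)), "left_lateral")
  expect_equal(sample_posture(c(0, -1, 0)), "right_lateral")
  expect_equal(sample_posture(c(1, 0, 0)), "non_lying")
  expect_equal(sample_posture(c(-1, 0, 0)), "non_lying")
  th <- 50 * pi / 180
  expect_equal(sample_posture(c(0, cos(th), sin(th))), "left_lateral")
  expect_error(sample_posture(c(0, 0, 0)), "non-zero")
})

test_that("sample_posture equals the quoted-rule oracle on a spherical grid", {
  # 2 degree grid; skip points within 0.5 degrees of a decision boundary
  th <- seq(1, 179, by = 2) * pi / 180
  ph <- seq(0, 358, by = 2) * pi / 180
  grid <- expand.grid(th = th, ph = ph)
  g <- cbind(cos(grid$th),
             sin(grid$th) * cos(grid$ph),
             sin(grid$th) * sin(grid$ph))
  deg <- function(v) acos(pmin(1, pmax(-1, v))) * 180 / pi
  tx <- deg(g[, 1]); ty <- deg(g[, 2]); tz <- deg(g[, 3])
  off <- abs(tx - 48) > 0.5 & abs(tx - 120) > 0.5 &
    abs(ty - 65) > 0.5 & abs(ty - 111) > 0.5 & abs(tz - 60) > 0.5
  g <- g[off, ]
  got <- sample_posture(g)
  want <- apply(g, 1, oracle_posture)
  expect_identical(got, unname(want))
  # the labels partition the sphere: every vector got exactly one label
  expect_true(all(got %in% c("supine", "right_lateral", "left_lateral",
                             "prone", "non_lying")))
})

test_that("epoch labelling follows the majority rule with strict boundary", {
  fs <- 1  # 30 samples per epoch at 1 Hz keeps arithmetic transparent
  lab30 <- function(n_a, a, b) c(rep(a, n_a), rep(b, 30 - n_a))
  labs <- c(rep("supine", 30),              # 100%
            lab30(17, "supine", "left_lateral"),  # ~57%
            lab30(15, "supine", "left_lateral"))  # exactly 50/50
  ep <- label_epochs(labs, movement = c(FALSE, FALSE, FALSE), fs = fs)
  expect_equal(ep$label, c("supine", "supine", "transition"))
  # movement wins over posture content
  ep2 <- label_epochs(labs, movement = c(TRUE, FALSE, FALSE), fs = fs)
  expect_equal(ep2$label[1], "movement")
  # non-lying majority epochs are labelled non_lying
  ep3 <- label_epochs(rep("non_lying", 30), FALSE, fs = fs)
  expect_equal(ep3$label, "non_lying")
  # permutation of samples within an epoch changes nothing
  set.seed(2)
  shuffled <- c(sample(labs[1:30]), sample(labs[31:60]), sample(labs[61:90]))
  ep4 <- label_epochs(shuffled, c(FALSE, FALSE, FALSE), fs = fs)
  expect_identical(ep4$label, ep$label)
})

test_that("posture percentages cover posture-labelled epochs only", {
  labs <- c(rep("supine", 3), "prone", rep("transition", 4))
  pct <- posture_percentages(labs)
  expect_equal(unname(pct["supine"]), 75)
  expect_equal(unname(pct["prone"]), 25)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  pct2 <- posture_percentages(rep(c("supine", "right_lateral",
                                    "left_lateral", "prone"), 5))
  expect_equal(unname(pct2), rep(25, 4))
  # order invariance
  set.seed(3)
  expect_equal(posture_percentages(sample(labs)), pct)
  expect_warning(posture_percentages(rep("movement", 5)), "undefined")
})

test_that("classifier validation counts recall and precision per posture", {
  truth <- rep(c("supine", "right_lateral"), c(10, 10))
  pred <- truth
  pred[11] <- "supine"  # one right-lateral epoch mislabelled supine
  v <- validate_classifier(truth, pred)
  expect_equal(v$recall[v$posture == "right_lateral"], 0.9)
  expect_equal(v$precision[v$posture == "right_lateral"], 1.0)
  expect_equal(v$precision[v$posture == "supine"], 10 / 11)
  expect_true(is.na(v$recall[v$posture == "prone"]))
  v2 <- validate_classifier(truth, truth)
  expect_true(all(v2$recall[1:2] == 1) && all(v2$precision[1:2] == 1))
  expect_error(validate_classifier(c("supine"), c("sitting")), "vocabulary")
})

test_that("classify_posture recovers a clean synthetic night", {
  sched <- posture_schedule(make_block_schedule(blocks = 2, block_s = 600),
                            movement_bursts = data.frame(start_s = 300,
                                                         duration_s = 60))
  ga <- gen_accel(sched, noise_sd_g = 0.005, orientation_jitter_deg = 10,
                  seed = 42)
  ep <- classify_posture(ga$accel)
  expect_equal(nrow(ep), nrow(ga$truth))
  v <- validate_classifier(ga$truth$label, ep$label)
  expect_true(all(v$recall == 1))
  expect_true(all(v$precision == 1))
  # movement truth epochs are flagged
  expect_true(all(ep$label[ga$truth$label == "movement"] == "movement"))
})
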