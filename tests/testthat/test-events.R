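test_that("troughs are strict local minima with slope annotations", {
  # single parabolic valley
  d <- ((1:100) - 50)^2 / 1000
  cand <- find_troughs(d, c(10, 90), fs = 1000, slope_window_ms = 20)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$sample_index, 49L)   # 0-based
  expect_lt(cand$pre_slope, 0)
  expect_gt(cand$post_slope, 0)

  # monotone signal has no troughs
  expect_equal(nrow(find_troughs(1:100 / 10, c(0, 100), 1000, 20)), 0L)

  # two valleys, ordered by index
  d2 <- c(((1:60) - 30)^2, ((1:60) - 25)^2 + 10) / 1000
  cand2 <- find_troughs(d2, c(0, 120), 1000, 20)
  expect_equal(cand2$sample_index, c(29L, 84L))

  expect_error(find_troughs(d, c(10, 12), 1000, 20), "3 samples")
  expect_error(find_troughs(d, c(10, 90), 1000, 0), "> 0")
})

test_that("strike selection takes the first trough with a sharp drop", {
  cands <- data.frame(sample_index = c(10L, 40L),
                      value = c(-0.01, -0.02),
                      pre_slope = c(-0.5, -0.3), post_slope = c(0.1, 0.4))
  expect_equal(detect_strike(cands, 0.1)$sample_index, 10L)

  # a shallow first trough is passed over
  cands$pre_slope <- c(-0.01, -0.5)
  expect_equal(detect_strike(cands, 0.1)$sample_index, 40L)

  err <- tryCatch(detect_strike(cands, 0.9), gait_detection_failure = identity)
  expect_s3_class(err, "gait_detection_failure")
  expect_equal(nrow(err$candidates), 2L)
  expect_error(detect_strike(cands[0, ], 0.1), "no trough")
})

test_that("off selection takes the first rising trough after the strike", {
  cands <- data.frame(sample_index = c(5L, 20L, 60L),
                      value = c(-0.03, -0.01, -0.02),
                      pre_slope = c(-0.5, -0.02, -0.1),
                      post_slope = c(0.02, 0.01, 0.8))
  expect_equal(detect_off(cands, 0.1, after_index = 5L)$sample_index, 60L)
  # single qualifying candidate
  expect_equal(detect_off(cands[3, ], 0.1)$sample_index, 60L)
  # a notch on a steeply rising flank is not an off trough
  notch <- data.frame(sample_index = c(30L, 60L), value = c(-0.01, -0.02),
                      pre_slope = c(0.4, -0.1), post_slope = c(0.3, 0.5))
  expect_equal(detect_off(notch, 0.1, after_index = 0L)$sample_index, 60L)
  err <- tryCatch(detect_off(cands, 2.0, after_index = 5L),
                  gait_detection_failure = identity)
  expect_s3_class(err, "gait_detection_failure")
})

test_that("a trial yields complete physiologically ordered quadruples", {
  trial <- make_trial(gait_params(n_cycles = 5, seed = 2))
  det <- suppressWarnings(detect_gait_events(trial$heel_rec, trial$toe_rec))
  ev <- det$events
  expect_gt(nrow(ev), 0)
  expect_equal(nrow(ev) %% 4L, 0L)
  expect_true(all(diff(ev$time) > 0))
  labs <- matrix(ev$label, ncol = 4, byrow = TRUE)
  for (i in seq_len(nrow(labs))) {
    expect_identical(labs[i, ], c("HS", "TS", "HO", "TO"))
  }
})

test_that("a segmentation with no flat interval yields an empty sequence", {
  d <- displacement_trace("heel", 1000, rnorm(500), rnorm(500))
  seg_all1 <- binarize_jerk(c(1e-9, rep(1, 498)), r = 0.5, fs = 1000)
  seg_all1$flat_intervals <- seg_all1$flat_intervals[0, ]
  expect_warning(out <- detect_all(d, d, seg_all1, seg_all1, gait_config()),
                 "no flat interval")
  expect_equal(nrow(out), 0L)
})

test_that("events fed the true displacement land on the truth times", {
  p <- gait_params(n_cycles = 5, seed = 2, noise_sigma = 0, drift_amp = 0)
  traj <- heel_toe_trajectories(p)
  trial <- make_trial(p)
  cfg <- gait_config()
  seg_h <- segment_phases(trial$heel_rec)
  seg_t <- segment_phases(trial$toe_rec)
  disp_h <- displacement_trace("heel", 1000, traj$heel, traj$heel)
  disp_t <- displacement_trace("toe", 1000, traj$toe, traj$toe)
  ev <- suppressWarnings(detect_all(disp_h, disp_t, seg_h, seg_t, cfg))
  m <- match_events(ev, trial$truth, 100)
  expect_gt(nrow(m$pairs), 0)
  expect_lt(max(abs(m$pairs$diff)), 0.010)   # within 10 ms of truth
})

test_that("the noiseless pipeline recovers every event within 20 ms", {
  trial <- make_trial(gait_params(n_cycles = 6, seed = 5, noise_sigma = 0,
                                  drift_amp = 0))
  det <- suppressWarnings(detect_gait_events(trial$heel_rec, trial$toe_rec))
  m <- match_events(det$events, trial$truth)
  expect_gte(nrow(m$pairs), 4 * 4)          # at least 4 full interior cycles
  expect_lt(max(abs(m$pairs$diff)), 0.020)
})

test_that("moderate extra noise shifts detections by under 30 ms median", {
  base <- make_trial(gait_params(n_cycles = 5, seed = 4, noise_sigma = 0,
                                 drift_amp = 0))
  d0 <- suppressWarnings(detect_gait_events(base$heel_rec, base$toe_rec))
  noisy <- make_trial(gait_params(n_cycles = 5, seed = 4, noise_sigma = 0.3,
                                  drift_amp = 0))
  d1 <- suppressWarnings(detect_gait_events(noisy$heel_rec, noisy$toe_rec))
  m <- match_events(d1$events, d0$events, 100)
  expect_gt(nrow(m$pairs), 0)
  expect_lt(stats::median(abs(m$pairs$diff)), 0.030)
})
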