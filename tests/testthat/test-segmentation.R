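test_that("jerk magnitude matches the per-sample difference formula", {
  expect_equal(jerk_magnitude(rep(1, 5), rep(2, 5), rep(3, 5)), rep(0, 4))
  expect_equal(jerk_magnitude(c(0, 1, 1), c(0, 0, 0), c(0, 0, 0)), c(1, 0))
  set.seed(8)
  for (i in 1:10) {
    n <- sample(5:100, 1)
    ax <- rnorm(n); ay <- rnorm(n); az <- rnorm(n)
    expect_equal(jerk_magnitude(ax, ay, az), bf_jerk(ax, ay, az),
                 tolerance = 1e-12)
  }
  expect_error(jerk_magnitude(1:3, 1:3, 1:4), "equal length")
})

test_that("trailing-window smoothing matches its closed form", {
  expect_equal(smooth_jerk(rep(4, 50), 1000, 30), rep(4, 50))
  # impulse of height W -> plateau of 1 over [k, k+W-1]
  w <- 10
  ja <- numeric(50)
  ja[20] <- w
  out <- smooth_jerk(ja, 1000, window_ms = w)
  expect_equal(out[20:29], rep(1, 10))
  expect_equal(out[-(20:29)], rep(0, 40))
  # 30 ms at 1000 Hz is a 30-sample window
  set.seed(9)
  ja <- abs(rnorm(500))
  expect_equal(smooth_jerk(ja, 1000, 30), bf_smooth(ja, 30),
               tolerance = 1e-12)
  expect_error(smooth_jerk(ja, 1000, 0), "positive")
})

test_that("binarization thresholds at r times the maximum", {
  seg <- binarize_jerk(c(0, 0, 5, 5, 0), r = 0.5, fs = 1000)
  expect_identical(seg$binary, c(0L, 0L, 1L, 1L, 0L))
  expect_equal(seg$threshold_used, 2.5)
  expect_equal(seg$flat_intervals$start, c(0L, 4L))
  expect_equal(seg$flat_intervals$end, c(2L, 5L))
  expect_equal(seg$nonflat_intervals$start, 2L)

  # r -> 1: at most the argmax samples stay non-flat (strict inequality)
  ja <- c(1, 3, 2, 3, 1)
  seg1 <- binarize_jerk(ja, r = 0.999, fs = 1000)
  expect_lte(sum(seg1$binary), sum(ja == max(ja)))

  expect_error(binarize_jerk(rep(0, 5), 0.5), "degenerate")
  expect_error(binarize_jerk(c(1, 2), 1.5), "in \\(0, 1\\)")
})

test_that("flat and non-flat intervals tile the timeline", {
  set.seed(10)
  for (i in 1:10) {
    ja <- abs(rnorm(200)) + ifelse(runif(200) > 0.5, 3, 0)
    seg <- binarize_jerk(ja, 0.3, fs = 1000)
    iv <- rbind(seg$flat_intervals, seg$nonflat_intervals)
    iv <- iv[order(iv$start), ]
    expect_equal(iv$start[1], 0L)
    expect_equal(iv$end[nrow(iv)], length(ja))
    expect_true(all(iv$start[-1] == iv$end[-nrow(iv)]))  # no gap, no overlap
    in_flat <- logical(length(ja))
    for (k in seq_len(nrow(seg$flat_intervals))) {
      in_flat[(seg$flat_intervals$start[k] + 1):seg$flat_intervals$end[k]] <- TRUE
    }
    expect_identical(in_flat, seg$binary == 0L)
  }
})

test_that("increasing r never increases the non-flat sample count", {
  set.seed(11)
  ja <- abs(rnorm(500)) + rep(c(0, 4), each = 50)
  counts <- vapply(seq(0.05, 0.95, by = 0.1),
                   function(r) sum(binarize_jerk(ja, r, 1000)$binary),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("short segments are absorbed into their neighbours", {
  ja <- c(rep(0, 100), rep(5, 100), rep(0, 100))
  seg <- binarize_jerk(ja, 0.5, 1000)
  expect_identical(filter_short_segments(seg, 50)$binary, seg$binary)

  # 1-sample blip inside a flat run disappears
  ja2 <- rep(0.1, 200)
  ja2[100] <- 5
  seg2 <- filter_short_segments(binarize_jerk(ja2, 0.5, 1000), 50)
  expect_equal(nrow(seg2$flat_intervals), 1L)
  expect_equal(sum(seg2$binary), 0L)

  # property: all interior intervals at least min_ms long
  set.seed(12)
  for (i in 1:5) {
    ja3 <- abs(rnorm(1000)) + 3 * rbinom(1000, 1, 0.5)
    seg3 <- filter_short_segments(binarize_jerk(ja3, 0.5, 1000), 50)
    iv <- rbind(seg3$flat_intervals, seg3$nonflat_intervals)
    iv <- iv[order(iv$start), ]
    lens <- iv$end - iv$start
    if (nrow(iv) > 2) expect_true(all(lens[2:(nrow(iv) - 1)] >= 50))
  }
})

test_that("segment_phases marks stance quiet and swing active", {
  trial <- make_trial(quick_params(noise_sigma = 0, drift_amp = 0))
  seg <- segment_phases(trial$heel_rec)
  # heel contact spans [k + 0.2, k + 0.65); mid-stance must be flat,
  # mid-swing must be active
  mid_stance <- round((0.4 + 1:3) * 1000)
  mid_swing <- round((0.95 + 1:3) * 1000)
  expect_true(all(seg$binary[mid_stance] == 0))
  expect_true(all(seg$binary[mid_swing] == 1))
})
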