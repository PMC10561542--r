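test_that("filter initialization follows the baseline statistics", {
  set.seed(1)
  base <- rnorm(500)
  st <- init_trend_filter(base, fs = 1000)
  expect_equal(st$X, c(0, 0))
  expect_equal(st$R, var(base))
  expect_equal(st$R, 1, tolerance = 0.2)        # unit-variance baseline
  expect_identical(st$P, st$Q)
  expect_equal(st$Q[1, 1], var(diff(base)))
  expect_equal(st$Q[2, 2], var(diff(base)) / 100)  # tau = 10
  expect_error(init_trend_filter(rep(2, 500), 1000), "variance")
  expect_error(init_trend_filter(rnorm(50), 1000), "100 ms")
})

test_that("prediction applies the constant-velocity model", {
  st <- init_trend_filter(rnorm(200), 1000)
  st$X <- c(1, 0.5)
  expect_equal(kalman_predict(st)$X, c(1.5, 0.5))
  st$X <- c(0, 0)
  expect_equal(kalman_predict(st)$X, c(0, 0))
  st$P <- diag(2); st$Q <- matrix(0, 2, 2)
  expect_equal(kalman_predict(st)$P, matrix(c(2, 1, 1, 1), 2))
})

test_that("update decays the gain and ignores zero innovation", {
  st <- init_trend_filter(rnorm(200), 1000)
  # fresh filter (Delta = 0): alpha = 1 so a unit innovation with P = diag(1, 0),
  # R -> 0 moves the power estimate fully
  st$P <- diag(c(1, 0)); st$R <- 1e-12; st$delta_steps <- 0L
  st1 <- kalman_update(st, z = st$X[1] + 1)
  expect_equal(st1$X[1], 1, tolerance = 1e-6)
  # at Delta = delta * Fs steps the gain is scaled by exp(-1)
  st$delta_steps <- 100L                         # delta = 100 ms at 1 kHz
  st2 <- kalman_update(st, z = st$X[1] + 1)
  expect_equal(st2$X[1], exp(-1), tolerance = 1e-6)
  # zero innovation leaves the state unchanged
  st$delta_steps <- 0L
  st3 <- kalman_update(st, z = st$X[1])
  expect_equal(st3$X, st$X)
  # degenerate innovation variance errors
  st$P <- matrix(0, 2, 2); st$R <- 0
  expect_error(kalman_update(st, 1), "variance")
})

test_that("with no process noise and huge observation noise the state freezes", {
  set.seed(2)
  st <- init_trend_filter(rnorm(300), 1000)
  st$Q <- matrix(0, 2, 2); st$R <- 1e12
  for (z in rnorm(200, mean = 5)) {
    st <- kalman_predict(st)
    st <- kalman_update(st, z)
  }
  expect_equal(st$X, c(0, 0), tolerance = 1e-6)
})

test_that("threshold calibration pools electrode baselines into a beta fit", {
  # identical unit-sd baselines: the threshold equals the common 95% value
  set.seed(3)
  b <- rnorm(2000)
  thr <- calibrate_threshold(list(b, b, b))
  expect_equal(thr, sd(b) * qnorm(0.95), tolerance = 1e-9)
  expect_error(calibrate_threshold(list(b)), ">= 2")
  # per-electrode values drawn from a known beta: the fitted 99% quantile
  # tracks the true quantile
  set.seed(4)
  x <- rbeta(400, 4, 2)
  baselines <- lapply(x, function(v) rnorm(4000, sd = v / qnorm(0.95)))
  thr2 <- calibrate_threshold(baselines)
  expect_equal(thr2, qbeta(0.99, 4, 2), tolerance = 0.05)
})

test_that("null traces at baseline statistics produce no change points", {
  set.seed(5)
  time_ms <- seq(-2000, 995, by = 20)
  n_rep <- 400
  thr <- 1.645           # typical calibrated threshold for unit-sd baselines
  false_changes <- 0
  for (r in seq_len(n_rep)) {
    trace <- rnorm(length(time_ms), sd = 0.15)   # trial-averaged noise scale
    cps <- detect_change_points(trace, time_ms, c(-2000, -1500), thr)
    false_changes <- false_changes + cps$responsive
  }
  expect_lte(false_changes / n_rep, 0.01)
})

test_that("steps and ramps are localized within 50 ms with correct slopes", {
  set.seed(6)
  time_ms <- seq(-2000, 999)
  base_sd <- 0.05
  # +10 baseline-sd step at +100 ms
  trace <- rnorm(length(time_ms), sd = base_sd)
  trace[time_ms >= 100] <- trace[time_ms >= 100] + 10 * base_sd
  cps <- detect_change_points(trace, time_ms, c(-2000, -1500),
                              threshold = 1.645 * base_sd * 4)
  expect_true(cps$responsive)
  expect_lt(abs(cps$change_points$time_ms[1] - 100), 50)
  # noiseless-in-slope ramp from -500 ms at 2 units/s
  trace2 <- rnorm(length(time_ms), sd = 0.01)
  ramp <- time_ms >= -500
  trace2[ramp] <- trace2[ramp] + 2 * (time_ms[ramp] + 500) / 1000
  cps2 <- detect_change_points(trace2, time_ms, c(-2000, -1500),
                               threshold = 0.06)
  expect_lt(abs(cps2$change_points$time_ms[1] + 500), 50)
  ramp_seg <- subset(cps2$segments, end_ms - start_ms > 300)
  expect_equal(ramp_seg$slope_per_s[nrow(ramp_seg)], 2, tolerance = 0.2)
})

test_that("landmarks describe a triangular pulse and censor open ends", {
  set.seed(7)
  time_ms <- seq(-2000, 999)
  base_sd <- 0.02
  tri <- function(t) {
    y <- pmin((t + 100) / 300 * 3, 3 - (t - 200) / 300 * 3)
    pmax(y, 0)
  }
  trace <- rnorm(length(time_ms), sd = base_sd) + tri(time_ms)
  cps <- detect_change_points(trace, time_ms, c(-2000, -1500), threshold = 0.2)
  lm <- extract_landmarks(trace, time_ms, cps)
  expect_lt(abs(lm$start_ms + 100), 50)
  expect_lt(abs(lm$peak_ms - 200), 50)
  expect_lt(abs(lm$end_ms - 500), 50)
  expect_gt(lm$onset_slope, 0)
  expect_lt(lm$offset_slope, 0)
  # symmetric pulse: |onset slope| and |offset slope| agree within 15%
  expect_lt(abs(abs(lm$onset_slope) - abs(lm$offset_slope)) /
              abs(lm$onset_slope), 0.15)
  # pulse still elevated at the trace end is right-censored
  trace2 <- rnorm(length(time_ms), sd = base_sd) +
    pmax(0, (time_ms - 0) / 1000 * 3)
  cps2 <- detect_change_points(trace2, time_ms, c(-2000, -1500), threshold = 0.2)
  lm2 <- extract_landmarks(trace2, time_ms, cps2)
  expect_true(lm2$censored)
  expect_identical(lm2$end_ms, Inf)
  # non-responsive traces have no landmarks
  flat <- rnorm(length(time_ms), sd = base_sd)
  cps3 <- detect_change_points(flat, time_ms, c(-2000, -1500), threshold = 1)
  expect_error(extract_landmarks(flat, time_ms, cps3), "not responsive")
})

test_that("planted template landmarks are recovered from averaged profiles", {
  set.seed(8)
  tm <- canonical_templates()[4, ]           # start -380, peak 110, end 640
  g <- generate_ersp_profiles(15, templates = tm, snr = 5, n_trials = 130,
                              time_ms = seq(-2000, 995, by = 5))
  # the trace returns to baseline where the falling slope line reaches zero,
  # which may precede the nominal end landmark
  true_end <- min(tm$end_ms,
                  tm$peak_ms + 1000 * tm$onset_slope *
                    (tm$peak_ms - tm$start_ms) / 1000 / abs(tm$offset_slope))
  errs <- sapply(seq_len(15), function(i) {
    tr <- g$profiles[i, ]
    cps <- detect_change_points(tr, g$time_ms, c(-2000, -1500), threshold = 0.2)
    lm <- extract_landmarks(tr, g$time_ms, cps)
    c(start = lm$start_ms - tm$start_ms,
      peak = lm$peak_ms - tm$peak_ms,
      end = lm$end_ms - true_end)
  })
  expect_lt(median(abs(errs["start", ])), 50)
  expect_lt(median(abs(errs["peak", ])), 50)
  expect_lt(median(abs(errs["end", ])), 50)
})
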