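# amplitude of a single frequency component (discrete Fourier projection)
tone_amp <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  2 * abs(mean(x * exp(-2i * pi * f * t)))
}

make_rec <- function(sig, fs = 1000, grid = NULL) {
  n <- nrow(sig)
  ecog_recording(sig, fs, data.frame(
    id = sprintf("e%02d", seq_len(n)), participant = "S1",
    hemisphere = rep(c("L", "R"), length.out = n),
    grid = grid %||% rep("G1", n), surface = TRUE, valid = TRUE))
}

test_that("line noise is attenuated by at least 20 dB", {
  set.seed(1)
  fs <- 1000; n <- 10 * fs
  t <- (seq_len(n) - 1) / fs
  sig <- rbind(5 * sin(2 * pi * 60 * t) + rnorm(n),
               5 * sin(2 * pi * 60 * t) + rnorm(n))
  out <- preprocess_neural(make_rec(sig))
  for (e in 1:2) {
    before <- tone_amp(sig[e, ], 60, fs)
    after <- tone_amp(out$signal[e, ], 60, fs)
    expect_lt(20 * log10(after / before), -20)
  }
})

test_that("spiky channels are flagged by the kurtosis screen", {
  set.seed(2)
  fs <- 1000; n <- 10 * fs
  sig <- matrix(rnorm(6 * n), 6, n)
  spikes <- sample(n, 25)
  sig[3, spikes] <- sig[3, spikes] + 40
  out <- preprocess_neural(make_rec(sig, grid = rep(c("G1", "G2"), each = 3)))
  expect_false(out$electrode_meta$valid[3])
  expect_true(all(out$electrode_meta$valid[-3]))
  # manual overrides are honored
  out2 <- preprocess_neural(make_rec(sig, grid = rep(c("G1", "G2"), each = 3)),
                            manual_bad = "e05")
  expect_false(out2$electrode_meta$valid[5])
})

test_that("grid-wise CAR cancels signals shared within a grid", {
  set.seed(3)
  fs <- 1000; n <- 5 * fs
  common <- rnorm(n)
  sig <- rbind(common, common, common, rnorm(n))
  out <- preprocess_neural(make_rec(sig, grid = c("G1", "G1", "G1", "G2")),
                           notch_freqs = numeric(0))
  expect_lt(sd(out$signal[1, ]), 1e-8)
  expect_lt(sd(out$signal[2, ]), 1e-8)
  expect_gt(sd(out$signal[4, ]), 0)  # singleton grid loses only its own mean
  expect_error(preprocess_neural(make_rec(sig, grid = rep(NA_character_, 4))),
               "grid")
})

test_that("recordings above 1 kHz are antialiased and downsampled", {
  set.seed(4)
  fs <- 2000; n <- 4 * fs
  t <- (seq_len(n) - 1) / fs
  sig <- matrix(rep(sin(2 * pi * 100 * t), 2), 2, byrow = TRUE) +
    matrix(rnorm(2 * n, sd = 0.1), 2)
  out <- preprocess_neural(make_rec(sig, fs = fs))
  expect_equal(out$sampling_rate, 1000)
  expect_equal(ncol(out$signal), n / 2, tolerance = 2)
  expect_error(preprocess_neural(make_rec(sig, fs = 500)), ">= 1000")
})

test_that("high-gamma extraction recovers amplitude modulation", {
  set.seed(5)
  fs <- 1000; n <- 20 * fs
  t <- (seq_len(n) - 1) / fs
  # pure 100 Hz tone: envelope is flat away from the edges
  tone <- 2 * sin(2 * pi * 100 * t)
  hg <- extract_high_gamma(make_rec(rbind(tone, tone)))
  mid <- (2 * fs):(18 * fs)
  expect_lt(sd(hg$amplitude[1, mid]) / mean(hg$amplitude[1, mid]), 0.05)
  expect_gt(mean(hg$amplitude[1, mid]), 0)
  # zero signal gives zero amplitude
  hg0 <- extract_high_gamma(make_rec(matrix(0, 2, 10 * fs)))
  expect_lt(max(hg0$amplitude), 1e-10)
  # amplitude-modulated band noise: extracted envelope tracks the modulator
  mod <- 1 + 0.6 * sin(2 * pi * 0.25 * t)
  carrier <- hgspeech:::bandlimited_noise(n, fs, c(80, 140))
  am <- matrix(rep(3 * mod * carrier, 2), 2, byrow = TRUE)
  hg2 <- extract_high_gamma(make_rec(am))
  smooth <- function(x) stats::filter(x, rep(1 / 300, 300), sides = 2)
  r <- cor(as.numeric(smooth(hg2$amplitude[1, mid])), mod[mid],
           use = "complete.obs")
  expect_gt(r, 0.9)
  expect_error(extract_high_gamma(make_rec(matrix(0, 1, 50))), "warm-up")
})

test_that("epochs are baseline z-scored with the documented geometry", {
  set.seed(6)
  fs <- 1000
  n <- 30 * fs
  amp <- matrix(abs(rnorm(2 * n, mean = 5)), 2, n)
  hg <- make_hg_series(amp, fs)
  trials <- data.frame(stimulus_onset = c(5, 15), voice_onset = c(5.9, 15.9),
                       syllable = c("baeg", "gib"),
                       consonant_pair = c("b-g", "g-b"), vowel = c("ae", "i"))
  ep <- epoch_and_normalize(hg, trials)
  expect_equal(dim(ep$power), c(2, 2, 3000))  # 3 s at 1 kHz
  expect_equal(ep$time_ms[1], -2000)
  # the pre-stimulus baseline window itself re-scores to mean 0 / sd 1
  for (e in 1:2) for (tr in 1:2) {
    so <- trials$stimulus_onset[tr]; vo <- trials$voice_onset[tr]
    bsel <- ep$time_ms >= (so - 0.5 - vo) * 1000 & ep$time_ms < (so - vo) * 1000
    expect_equal(mean(ep$power[e, tr, bsel]), 0, tolerance = 1e-9)
    expect_equal(sd(ep$power[e, tr, bsel]), 1, tolerance = 1e-9)
  }
})

test_that("a step of +3 baseline sd appears as z of 3 and bad trials drop", {
  fs <- 1000; n <- 20 * fs
  set.seed(7)
  base <- rnorm(n, mean = 10, sd = 2)
  amp <- base
  vo <- 8
  amp[(vo * fs):n] <- amp[(vo * fs):n] + 6      # +3 baseline sd after onset
  hg <- make_hg_series(rbind(amp), fs)
  trials <- data.frame(stimulus_onset = 7, voice_onset = vo)
  ep <- epoch_and_normalize(hg, trials)
  post <- ep$time_ms > 50
  expect_equal(mean(ep$power[1, 1, post]), 3, tolerance = 0.2)
  # out-of-bounds trial is dropped with a warning
  trials2 <- rbind(trials, data.frame(stimulus_onset = 19.2, voice_onset = 19.9))
  expect_warning(ep2 <- epoch_and_normalize(hg, trials2), "dropped")
  expect_equal(dim(ep2$power)[2], 1)
  # constant baseline triggers the invalid electrode-trial path
  flat <- make_hg_series(rbind(rep(1, n)), fs)
  expect_warning(ep3 <- epoch_and_normalize(flat, trials), "zero baseline")
  expect_true(all(is.na(ep3$power)))
})

test_that("ERSP is the trial mean and is linear in trial subsets", {
  set.seed(8)
  ep <- make_test_epochs(3, 20)
  er <- compute_ersp(ep)
  expect_equal(er$mean_power[2, ], colMeans(ep$power[2, , ]))
  # concatenation linearity: weighted mean of subset ERSPs
  ep_a <- ep; ep_a$power <- ep$power[, 1:8, , drop = FALSE]
  ep_b <- ep; ep_b$power <- ep$power[, 9:20, , drop = FALSE]
  blended <- (8 * compute_ersp(ep_a)$mean_power +
                12 * compute_ersp(ep_b)$mean_power) / 20
  expect_equal(er$mean_power, blended, tolerance = 1e-12)
})

test_that("responsiveness screening separates planted from flat electrodes", {
  set.seed(9)
  ep <- make_test_epochs(6, 30, peak_z = 4)
  ep$power[5, , ] <- rnorm(length(ep$power[5, , ]))  # flat noise electrode
  ep$power[6, , ] <- rnorm(length(ep$power[6, , ]))
  er <- compute_ersp(ep)
  scr <- screen_responsive(er, ep)
  expect_true(all(scr$responsive[1:4]))
  expect_false(any(scr$responsive[5:6]))
})

test_that("screening false-positive rate on pure noise is controlled", {
  set.seed(10)
  n_el <- 100
  ep <- make_test_epochs(n_el, 30, peak_z = 0)
  er <- compute_ersp(ep)
  scr <- screen_responsive(er, ep)
  expect_lte(mean(scr$flag_ci), 0.05)
  expect_lte(mean(scr$responsive), 0.02)
})
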