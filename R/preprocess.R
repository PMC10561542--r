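# Neural signal conditioning: downsampling, DC removal, notch filtering,
# kurtosis bad-channel screening, grid-wise common average referencing,
# Hilbert high-gamma extraction, and baseline z-scored epoching.

#' Condition a raw multichannel recording
#'
#' Applies, in order: antialiased downsampling to `target_rate`; per-channel
#' DC removal (subtracting the channel mean over the whole record);
#' zero-phase IIR notch filtering at the line frequency and its harmonics;
#' a kurtosis screen that flags channels whose sample kurtosis exceeds
#' `median + kurtosis_mads * MAD` across channels (plus any manual list);
#' and a grid-wise common average reference computed from the valid
#' channels of each grid.
#'
#' @param rec an [ecog_recording()].
#' @param target_rate working sampling rate (Hz), default 1000.
#' @param notch_freqs frequencies (Hz) to notch; harmonics above Nyquist are
#'   skipped.
#' @param notch_halfwidth half-width (Hz) of each notch stop band.
#' @param kurtosis_mads robust kurtosis bound in MAD units.
#' @param manual_bad character vector of electrode ids to force-invalidate
#'   (manually verified removals).
#' @return an [ecog_recording()] at `target_rate` with updated `valid`
#'   flags; invalid channels are retained (flagged) but excluded from the
#'   reference.
#' @export
preprocess_neural <- function(rec, target_rate = 1000,
                              notch_freqs = c(60, 120, 180, 240),
                              notch_halfwidth = 2,
                              kurtosis_mads = 5,
                              manual_bad = NULL) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (rec$sampling_rate < target_rate) {
    stop("recording must be sampled at >= ", target_rate, " Hz")
  }
  sig <- rec$signal
  fs <- rec$sampling_rate
  if (fs > target_rate) {
    frac <- rational_ratio(target_rate / fs)
    sig <- t(apply(sig, 1, function(x) {
      signal::resample(x, frac[1], frac[2])
    }))
    fs <- target_rate
  }
  sig <- sig - rowMeans(sig)
  ny <- fs / 2
  for (f0 in notch_freqs) {
    if (f0 >= ny) next
    bf <- signal::butter(2, c(f0 - notch_halfwidth, f0 + notch_halfwidth) / ny,
                         type = "stop")
    sig <- t(apply(sig, 1, function(x) signal::filtfilt(bf, x)))
  }
  meta <- rec$electrode_meta
  kur <- apply(sig, 1, sample_kurtosis)
  bound <- stats::median(kur, na.rm = TRUE) +
    kurtosis_mads * stats::mad(kur, na.rm = TRUE)
  bad <- !is.na(kur) & kur > bound
  if (!is.null(manual_bad)) bad <- bad | meta$id %in% manual_bad
  meta$valid <- meta$valid & !bad
  if (!any(meta$valid)) stop("all channels flagged invalid")
  if (any(is.na(meta$grid)) || any(!nzchar(meta$grid))) {
    stop("missing grid labels")
  }
  for (g in unique(meta$grid)) {
    in_grid <- meta$grid == g
    ref_rows <- in_grid & meta$valid
    if (!any(ref_rows)) next
    ref <- colMeans(sig[ref_rows, , drop = FALSE])
    sig[in_grid, ] <- sweep(sig[in_grid, , drop = FALSE], 2, ref)
  }
  ecog_recording(sig, fs, meta)
}

# small rational approximation p/q of a rate ratio for signal::resample
rational_ratio <- function(ratio, max_den = 1000) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(ratio * q)
    if (p < 1) next
    e <- abs(ratio - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(p, q) }
    if (err < 1e-12) break
  }
  best
}

#' Extract high-gamma analytic amplitude
#'
#' Bandpass filters each channel into `n_bands` logarithmically spaced bands
#' spanning `band` (70-150 Hz by default) with zero-phase Butterworth
#' filters, takes the absolute value of the analytic signal of each band as
#' its amplitude envelope, and averages the envelopes across bands.
#'
#' @param rec a conditioned [ecog_recording()] at the working rate.
#' @param band numeric length-2 overall frequency span (Hz).
#' @param n_bands number of logarithmic sub-bands (default 8).
#' @param order Butterworth order per band (applied forward and backward).
#' @return object of class `hg_series`: list with `amplitude` (electrodes x
#'   samples), `sampling_rate`, `electrode_meta`.
#' @export
extract_high_gamma <- function(rec, band = c(70, 150), n_bands = 8, order = 4) {
  stopifnot(inherits(rec, "ecog_recording"))
  fs <- rec$sampling_rate
  n <- ncol(rec$signal)
  if (n < 20 * fs / band[1]) stop("record shorter than the filter warm-up")
  edges <- exp(seq(log(band[1]), log(band[2]), length.out = n_bands + 1L))
  ny <- fs / 2
  filters <- lapply(seq_len(n_bands), function(b) {
    signal::butter(order, c(edges[b], edges[b + 1L]) / ny, type = "pass")
  })
  amp <- matrix(0, nrow(rec$signal), n)
  for (e in seq_len(nrow(rec$signal))) {
    acc <- numeric(n)
    for (bf in filters) {
      xb <- signal::filtfilt(bf, rec$signal[e, ])
      acc <- acc + Mod(analytic_signal(xb))
    }
    amp[e, ] <- acc / n_bands
  }
  structure(list(amplitude = amp, sampling_rate = fs,
                 electrode_meta = rec$electrode_meta),
            class = "hg_series")
}

#' Epoch high-gamma power and z-score to the trial baseline
#'
#' Cuts voice-onset-aligned epochs (default -2000 to +1000 ms, half-open)
#' out of the continuous high-gamma amplitude and re-references each
#' electrode-trial as a z-score relative to that trial's baseline: the
#' 500 ms immediately preceding stimulus presentation by default
#' (`baseline_mode = "pre_stimulus"`), or the earliest 500 ms of the epoch
#' (`baseline_mode = "epoch_start"`).
#'
#' @param hg an `hg_series` from [extract_high_gamma()].
#' @param trials trial table with `stimulus_onset` and `voice_onset`
#'   (seconds) plus label columns.
#' @param epoch_window length-2 ms window relative to voice onset,
#'   half-open `[start, end)`.
#' @param baseline_ms length of the baseline window (ms).
#' @param baseline_mode where the baseline sits (see above).
#' @return object of class `hg_epochs`: list with `power` (electrodes x
#'   trials x timepoints, z-units), `time_ms`, `trials` (rows actually
#'   used), `sampling_rate`, `electrode_meta`, `baseline`.
#' @export
epoch_and_normalize <- function(hg, trials,
                                epoch_window = c(-2000, 1000),
                                baseline_ms = 500,
                                baseline_mode = c("pre_stimulus", "epoch_start")) {
  stopifnot(inherits(hg, "hg_series"))
  baseline_mode <- match.arg(baseline_mode)
  fs <- hg$sampling_rate
  nsamp <- ncol(hg$amplitude)
  n_elec <- nrow(hg$amplitude)
  ep_idx <- seq(round(epoch_window[1] / 1000 * fs),
                round(epoch_window[2] / 1000 * fs) - 1L)
  time_ms <- ep_idx / fs * 1000
  nb <- round(baseline_ms / 1000 * fs)

  keep <- logical(nrow(trials))
  power <- array(NA_real_, c(n_elec, nrow(trials), length(ep_idx)))
  for (tr in seq_len(nrow(trials))) {
    vo <- round(trials$voice_onset[tr] * fs)
    idx <- vo + ep_idx + 1L
    if (baseline_mode == "pre_stimulus") {
      so <- round(trials$stimulus_onset[tr] * fs)
      bidx <- seq(so - nb, so - 1L) + 1L
    } else {
      bidx <- idx[seq_len(nb)]
    }
    if (min(idx, bidx) < 1L || max(idx, bidx) > nsamp) {
      warning("trial ", tr, " window out of bounds; trial dropped")
      next
    }
    keep[tr] <- TRUE
    for (e in seq_len(n_elec)) {
      b <- hg$amplitude[e, bidx]
      s <- stats::sd(b)
      if (!is.finite(s) || s == 0) {
        warning("zero baseline sd for electrode ", e, ", trial ", tr,
                "; electrode-trial marked invalid")
        next
      }
      power[e, tr, ] <- (hg$amplitude[e, idx] - mean(b)) / s
    }
  }
  power <- power[, keep, , drop = FALSE]
  structure(list(power = power, time_ms = time_ms,
                 trials = trials[keep, , drop = FALSE],
                 sampling_rate = fs,
                 electrode_meta = hg$electrode_meta,
                 baseline = list(ms = baseline_ms, mode = baseline_mode)),
            class = "hg_epochs")
}

#' Trial-averaged ERSP
#'
#' Averages baseline z-scored high-gamma epochs over trials to form each
#' electrode's event-related spectral perturbation time-course.
#'
#' @param epochs an `hg_epochs` object.
#' @return object of class `ersp`: list with `mean_power` (electrodes x
#'   timepoints), `time_ms`, `n_trials`, `sampling_rate`, `electrode_meta`.
#' @export
compute_ersp <- function(epochs) {
  stopifnot(inherits(epochs, "hg_epochs"))
  mp <- apply(epochs$power, c(1, 3), mean, na.rm = TRUE)
  structure(list(mean_power = mp, time_ms = epochs$time_ms,
                 n_trials = dim(epochs$power)[2],
                 sampling_rate = epochs$sampling_rate,
                 electrode_meta = epochs$electrode_meta),
            class = "ersp")
}

#' Screen electrodes for task responsiveness
#'
#' Two-stage screen on the ERSP. Stage 1 (CI screen): an electrode passes if
#' any post-baseline point of its ERSP leaves the 95% confidence band
#' (mean +/- 1.96 sd) of its single-trial z-scored baseline activity — the
#' band is close to [-1.96, 1.96] by construction of the z-scoring, so a
#' trial-averaged trace (whose noise shrinks with the trial count) crosses
#' it only for genuine task deviations. Stage 2 (trend
#' screen): the Kalman-filter change-point analysis must report at least one
#' change after the baseline. An electrode is responsive iff both flags are
#' true.
#'
#' @param ersp an [compute_ersp()] result.
#' @param epochs the matching `hg_epochs` (used to calibrate the global
#'   change threshold from single-trial baselines when `threshold` is NULL).
#' @param ersp_baseline_ms length-2 ms window on the epoch axis treated as
#'   the ERSP baseline segment (default the earliest 500 ms).
#' @param threshold optional global change threshold (z-units); calibrated
#'   with [calibrate_threshold()] when NULL and more than one electrode is
#'   present.
#' @param trend_config a [trend_config()].
#' @return data.frame with columns `id`, `flag_ci`, `flag_trend`,
#'   `responsive`, plus the threshold used as an attribute.
#' @export
screen_responsive <- function(ersp, epochs,
                              ersp_baseline_ms = NULL,
                              threshold = NULL,
                              trend_config = trend_config_default()) {
  stopifnot(inherits(ersp, "ersp"))
  if (is.null(ersp_baseline_ms)) {
    ersp_baseline_ms <- c(min(ersp$time_ms), min(ersp$time_ms) + 500)
  }
  post <- ersp$time_ms >= ersp_baseline_ms[2]
  n_elec <- nrow(ersp$mean_power)
  if (is.null(threshold)) {
    if (n_elec < 2L) stop("threshold calibration needs >= 2 electrodes")
    baselines <- trial_baseline_values(epochs)
    threshold <- calibrate_threshold(baselines)
  }
  trial_bl <- trial_baseline_values(epochs)
  flag_ci <- flag_trend <- logical(n_elec)
  for (e in seq_len(n_elec)) {
    tr <- ersp$mean_power[e, ]
    m <- mean(trial_bl[[e]]); s <- stats::sd(trial_bl[[e]])
    flag_ci[e] <- any(tr[post] > m + 1.96 * s | tr[post] < m - 1.96 * s)
    cps <- detect_change_points(tr, ersp$time_ms,
                                baseline_window = ersp_baseline_ms,
                                threshold = threshold,
                                config = trend_config)
    flag_trend[e] <- cps$responsive
  }
  out <- data.frame(id = ersp$electrode_meta$id, flag_ci = flag_ci,
                    flag_trend = flag_trend,
                    responsive = flag_ci & flag_trend)
  attr(out, "threshold") <- threshold
  out
}

# per-electrode single-trial z-scored baseline samples, concatenated across
# trials; used to calibrate the global change threshold
trial_baseline_values <- function(epochs) {
  fs <- epochs$sampling_rate
  nb <- round(epochs$baseline$ms / 1000 * fs)
  n_elec <- dim(epochs$power)[1]
  # the earliest epoch samples precede stimulus onset for typical reaction
  # times, so they carry the single-trial z-scored baseline statistics
  lapply(seq_len(n_elec), function(e) {
    v <- as.numeric(epochs$power[e, , seq_len(nb)])
    v[is.finite(v)]
  })
}
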