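# Synthetic ECoG sessions with planted temporal clusters and phonemic tuning.
#
# The generator emulates a CVC syllable repetition session: trials with
# stimulus onsets and truncated-normal reaction times, electrodes whose
# speech-locked high-gamma responses follow one of six canonical temporal
# templates, multiplicative label tuning for consonant-pair / vowel /
# syllable identity with a configurable hemispheric bias, a 70-150 Hz
# band-limited carrier plus 1/f background and optional line noise, and an
# audio track with voicing bursts at the planted voice onsets.

#' Six canonical speech-locked response templates
#'
#' Timing landmarks (ms relative to voice onset) and activity slopes (1/s,
#' in normalized-power units) of six characteristic high-gamma response
#' profiles observed during syllable production, spanning speech-preparatory
#' responses through post-production auditory responses. An infinite `end`
#' marks a response still elevated at the epoch end (right-censored).
#'
#' @return data.frame with columns `cluster`, `start_ms`, `onset_slope`,
#'   `peak_ms`, `offset_slope`, `end_ms`.
#' @export
canonical_templates <- function() {
  data.frame(
    cluster = 1:6,
    start_ms = c(-1040, -830, -710, -380, -50, 10),
    onset_slope = c(1.16, 1.27, 0.72, 1.13, 2.07, 1.35),
    peak_ms = c(-480, -340, 200, 110, 200, 570),
    offset_slope = c(-1.08, -0.70, -0.69, -1.2, -1.1, -1.33),
    end_ms = c(320, 800, Inf, 640, 680, Inf)
  )
}

#' Evaluate a response template on a time axis
#'
#' Builds the piecewise-linear profile implied by a row of
#' [canonical_templates()]: zero before `start_ms`, rising at `onset_slope`
#' to the peak, decaying at `offset_slope` afterwards, clipped at zero and
#' truncated at `end_ms` when finite.
#'
#' @param template one-row data.frame (or list) with the landmark fields.
#' @param time_ms numeric time axis in ms relative to voice onset.
#' @return numeric vector of non-negative normalized-power values.
#' @export
template_trace <- function(template, time_ms) {
  peak_amp <- template$onset_slope * (template$peak_ms - template$start_ms) / 1000
  rise <- template$onset_slope * (time_ms - template$start_ms) / 1000
  fall <- peak_amp + template$offset_slope * (time_ms - template$peak_ms) / 1000
  y <- pmax(0, pmin(rise, fall, peak_amp))
  y[time_ms < template$start_ms] <- 0
  if (is.finite(template$end_ms)) y[time_ms >= template$end_ms] <- 0
  y
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of a synthetic session. Defaults
#' follow the repetition-task design: five participants, reaction times
#' 900 +/- 200 ms (truncated at 300 ms), 130 analyzed first-word trials per
#' participant, six canonical response templates, and a 70-150 Hz carrier
#' with 1/f background noise.
#'
#' @param n_participants number of simulated participants.
#' @param electrodes_per_hemisphere electrodes per hemisphere per participant.
#' @param sampling_rate_neural neural sampling rate (Hz).
#' @param sampling_rate_audio audio sampling rate (Hz).
#' @param n_trials analyzed trials per participant.
#' @param reaction_time_mean,reaction_time_sd reaction time distribution (ms).
#' @param reaction_time_min truncation bound (ms) excluding nonphysical
#'   latencies.
#' @param stimulus_duration_s on-screen stimulus duration (s).
#' @param iti_range_s range (s) of the randomized gap appended after each
#'   trial's fixed presentation interval (values are drawn uniformly from the
#'   integer seconds in this range).
#' @param stimulus_set a [generate_stimulus_set()] result.
#' @param cluster_templates template landmark table; see
#'   [canonical_templates()].
#' @param cluster_mixture 2 x k matrix (rows "L","R") of per-hemisphere
#'   template probabilities; rows must sum to 1.
#' @param tuning list with per-unit vectors `fraction` (share of electrodes
#'   tuned), `effect` (fractional amplitude modulation for the preferred
#'   label), and `left_bias` (probability that a tuned electrode sits in the
#'   left hemisphere); units are "consonant", "vowel", "syllable".
#' @param response_gain peak fractional high-gamma modulation applied to the
#'   (unit-slope) template profile.
#' @param hg_amplitude baseline amplitude (uV) of the high-gamma carrier.
#' @param noise list: `pink_exponent`, `pink_amplitude` (uV sd),
#'   `line_amplitude` (uV, 60 Hz).
#' @param burst_duration_s duration of each voicing burst in the audio (s);
#'   utterance durations are not pinned down by the task design, so this is
#'   a free parameter.
#' @param seed integer seed; identical configs give bit-identical sessions.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 5,
                       electrodes_per_hemisphere = 20,
                       sampling_rate_neural = 1000,
                       sampling_rate_audio = 12000,
                       n_trials = 130,
                       reaction_time_mean = 900,
                       reaction_time_sd = 200,
                       reaction_time_min = 300,
                       stimulus_duration_s = 1,
                       iti_range_s = c(3, 5),
                       stimulus_set = generate_stimulus_set(),
                       cluster_templates = canonical_templates(),
                       cluster_mixture = NULL,
                       tuning = list(
                         fraction = c(consonant = 0.1, vowel = 0.1, syllable = 0.1),
                         effect = c(consonant = 0.5, vowel = 0.5, syllable = 0.5),
                         left_bias = c(consonant = 0.5, vowel = 0.5, syllable = 0.5)
                       ),
                       response_gain = 1.5,
                       hg_amplitude = 5,
                       noise = list(pink_exponent = 1, pink_amplitude = 5,
                                    line_amplitude = 0),
                       burst_duration_s = 0.45,
                       seed = 1L) {
  k <- nrow(cluster_templates)
  if (is.null(cluster_mixture)) {
    cluster_mixture <- matrix(1 / k, 2, k, dimnames = list(c("L", "R"), NULL))
  }
  cfg <- list(
    n_participants = n_participants,
    electrodes_per_hemisphere = electrodes_per_hemisphere,
    sampling_rate_neural = sampling_rate_neural,
    sampling_rate_audio = sampling_rate_audio,
    n_trials = n_trials,
    reaction_time_mean = reaction_time_mean,
    reaction_time_sd = reaction_time_sd,
    reaction_time_min = reaction_time_min,
    stimulus_duration_s = stimulus_duration_s,
    iti_range_s = iti_range_s,
    stimulus_set = stimulus_set,
    cluster_templates = cluster_templates,
    cluster_mixture = cluster_mixture,
    tuning = tuning,
    response_gain = response_gain,
    hg_amplitude = hg_amplitude,
    noise = noise,
    burst_duration_s = burst_duration_s,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$sampling_rate_neural <= 0 || cfg$sampling_rate_audio <= 0) {
    stop("sampling rates must be positive")
  }
  if (cfg$n_participants < 1L || cfg$electrodes_per_hemisphere < 1L) {
    stop("invalid config: need at least one participant and one electrode")
  }
  if (cfg$n_trials < 1L) stop("invalid config: zero trials")
  if (cfg$n_trials < nrow(cfg$stimulus_set$syllables)) {
    stop("n_trials must be at least the number of distinct syllables")
  }
  rs <- rowSums(cfg$cluster_mixture)
  if (any(abs(rs - 1) > 1e-8)) stop("cluster_mixture rows must sum to 1")
  if (ncol(cfg$cluster_mixture) != nrow(cfg$cluster_templates)) {
    stop("cluster_mixture columns must match the number of templates")
  }
  if (any(unlist(cfg$tuning$effect) < 0)) stop("tuning effects must be >= 0")
  invisible(cfg)
}

# truncated-normal reaction times (ms), lower truncation only
draw_reaction_times <- function(n, mean, sd, lower) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    out[need] <- stats::rnorm(length(need), mean, sd)
    need <- need[out[need] < lower]
  }
  out
}

#' Generate the trial table for one session
#'
#' Stimulus onsets follow the paced first-word-of-pair design: each trial
#' occupies the 1 s presentation, a 1.5 s gap, the (unsimulated) second
#' word's 1 s presentation, and a randomized inter-pair interval. Voice
#' onsets are the stimulus onsets plus truncated-normal reaction times, and
#' syllable labels are drawn balanced across the stimulus inventory.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `trial`, `syllable`, `consonant_pair`,
#'   `vowel`, `stimulus_onset`, `voice_onset` (times in seconds).
#' @export
generate_trials <- function(config) {
  syl <- config$stimulus_set$syllables
  n <- config$n_trials
  reps <- rep(seq_len(nrow(syl)), length.out = n)
  idx <- sample(reps)                     # balanced, permuted labels
  rt <- draw_reaction_times(n, config$reaction_time_mean,
                            config$reaction_time_sd, config$reaction_time_min)
  gaps <- config$stimulus_duration_s + 1.5 + config$stimulus_duration_s +
    sample(seq(config$iti_range_s[1], config$iti_range_s[2]), n, replace = TRUE)
  onset0 <- 4                              # lead-in so the first epoch fits
  stim <- onset0 + c(0, cumsum(gaps[-n]))
  data.frame(
    trial = seq_len(n),
    syllable = syl$syllable[idx],
    consonant_pair = syl$consonant_pair[idx],
    vowel = syl$vowel[idx],
    stimulus_onset = stim,
    voice_onset = stim + rt / 1000
  )
}

#' Synthesize the audio track for a trial table
#'
#' A near-silent Gaussian background with broadband voicing bursts (noise of
#' amplitude much larger than background) starting at each voice onset.
#' Overlapping bursts are merged with a warning.
#'
#' @param trials trial table with a `voice_onset` column (seconds); may have
#'   zero rows.
#' @param sampling_rate audio sampling rate (Hz).
#' @param burst_duration_s burst length (s).
#' @param burst_amplitude,background_amplitude amplitudes of the voicing
#'   noise and of the silent-background noise.
#' @param duration_s total duration (s); defaults to the last burst end plus
#'   two seconds.
#' @return numeric waveform with attribute `sampling_rate`.
#' @export
generate_audio <- function(trials, sampling_rate,
                           burst_duration_s = 0.45,
                           burst_amplitude = 0.5,
                           background_amplitude = 1e-4,
                           duration_s = NULL) {
  if (is.null(duration_s)) {
    duration_s <- if (nrow(trials)) max(trials$voice_onset) + burst_duration_s + 2 else 1
  }
  n <- ceiling(duration_s * sampling_rate)
  if (nrow(trials) && any(trials$voice_onset + burst_duration_s > duration_s)) {
    stop("trial voice onsets fall outside the session duration")
  }
  wav <- stats::rnorm(n, sd = background_amplitude)
  if (nrow(trials)) {
    on <- sort(trials$voice_onset)
    if (any(diff(on) < burst_duration_s)) {
      warning("overlapping voicing bursts merged")
    }
    voiced <- rep(FALSE, n)
    for (t0 in on) {
      i0 <- floor(t0 * sampling_rate) + 1L
      i1 <- min(n, i0 + round(burst_duration_s * sampling_rate) - 1L)
      voiced[i0:i1] <- TRUE
    }
    wav[voiced] <- stats::runif(sum(voiced), -1, 1) * burst_amplitude
  }
  attr(wav, "sampling_rate") <- sampling_rate
  wav
}

#' Multichannel ECoG recording container
#'
#' @param signal electrodes x samples numeric matrix (uV).
#' @param sampling_rate sampling rate (Hz).
#' @param electrode_meta data.frame with one row per electrode and columns
#'   `id`, `participant`, `hemisphere` ("L"/"R"), `grid`, `surface`
#'   (logical), `valid` (logical).
#' @return object of class `ecog_recording`.
#' @export
ecog_recording <- function(signal, sampling_rate, electrode_meta) {
  if (!is.matrix(signal)) stop("signal must be an electrodes x samples matrix")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (nrow(signal) != nrow(electrode_meta)) {
    stop("electrode_meta rows must match signal rows")
  }
  if (anyDuplicated(electrode_meta$id)) stop("duplicate electrode ids")
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 electrode_meta = electrode_meta),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat("ECoG recording:", nrow(x$signal), "electrodes x", ncol(x$signal),
      "samples @", x$sampling_rate, "Hz\n")
  invisible(x)
}

# draw electrode metadata + planted ground truth for one participant
plant_electrodes <- function(config, participant) {
  npe <- config$electrodes_per_hemisphere
  hemi <- rep(c("L", "R"), each = npe)
  n <- 2L * npe
  meta <- data.frame(
    id = sprintf("%s_E%03d", participant, seq_len(n)),
    participant = participant,
    hemisphere = hemi,
    grid = paste0(participant, "_", hemi, "1"),
    surface = TRUE,
    valid = TRUE
  )
  k <- nrow(config$cluster_templates)
  cl <- integer(n)
  for (h in c("L", "R")) {
    rows <- which(hemi == h)
    cl[rows] <- sample.int(k, length(rows), replace = TRUE,
                           prob = config$cluster_mixture[h, ])
  }
  tuned_unit <- rep(NA_character_, n)
  tuned_label <- rep(NA_character_, n)
  effect <- numeric(n)
  labels_of <- list(
    consonant = config$stimulus_set$consonant_pairs,
    vowel = config$stimulus_set$vowels,
    syllable = config$stimulus_set$syllables$syllable
  )
  free <- seq_len(n)
  for (u in names(config$tuning$fraction)) {
    n_u <- round(config$tuning$fraction[[u]] * n)
    if (n_u < 1L || !length(free)) next
    bias <- config$tuning$left_bias[[u]]
    w <- ifelse(hemi[free] == "L", bias, 1 - bias)
    if (all(w == 0)) w <- rep(1, length(free))
    pick <- free[sample.int(length(free), min(n_u, length(free)), prob = w)]
    tuned_unit[pick] <- u
    tuned_label[pick] <- sample(labels_of[[u]], length(pick), replace = TRUE)
    effect[pick] <- config$tuning$effect[[u]]
    free <- setdiff(free, pick)
  }
  meta$cluster <- cl
  meta$tuned_unit <- tuned_unit
  meta$tuned_label <- tuned_label
  meta$effect <- effect
  meta
}

#' Generate one synthetic session
#'
#' Produces the four linked artifacts for a single participant: the neural
#' recording, the audio waveform, the trial table, and the planted ground
#' truth. Each electrode's high-gamma response is implemented as amplitude
#' modulation of a 70-150 Hz band-limited noise carrier (so that the Hilbert
#' extraction path, not a shortcut, recovers it): the planted template is
#' summed at every trial's voice onset, scaled by `1 + effect` on trials
#' matching a tuned electrode's preferred label, and the modulated carrier
#' is added to 1/f background noise and optional 60 Hz line noise.
#'
#' @param config a [sim_config()].
#' @param participant participant id string (default "S1").
#' @param seed integer seed for this session; defaults to `config$seed`.
#'   Identical config + seed gives bit-identical outputs.
#' @return list with elements `recording` ([ecog_recording]), `audio`
#'   (waveform with `sampling_rate` attribute), `trials` (data.frame) and
#'   `ground_truth` (list with `electrodes` and `trials` data.frames).
#' @export
generate_session <- function(config, participant = "S1", seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  trials <- generate_trials(config)
  meta <- plant_electrodes(config, participant)
  fs <- config$sampling_rate_neural
  dur <- max(trials$voice_onset) + 3
  nsamp <- ceiling(dur * fs)
  t_ms <- ((seq_len(nsamp) - 1) / fs) * 1000   # ms from record start

  n_elec <- nrow(meta)
  sig <- matrix(0, n_elec, nsamp)
  # label-dependent response scale per trial per electrode is encoded in the
  # modulation envelope m(t); responses superpose across trials
  templ <- config$cluster_templates
  unit_col <- c(consonant = "consonant_pair", vowel = "vowel", syllable = "syllable")
  for (e in seq_len(n_elec)) {
    tpl <- templ[meta$cluster[e], ]
    m <- numeric(nsamp)
    for (tr in seq_len(nrow(trials))) {
      scale_tr <- 1
      if (!is.na(meta$tuned_unit[e])) {
        lab <- trials[[unit_col[[meta$tuned_unit[e]]]]][tr]
        if (lab == meta$tuned_label[e]) scale_tr <- 1 + meta$effect[e]
      }
      rel <- t_ms - trials$voice_onset[tr] * 1000
      span <- rel >= tpl$start_ms - 1 & rel <= min(tpl$end_ms, 1500)
      if (any(span)) {
        m[span] <- m[span] +
          config$response_gain * scale_tr * template_trace(tpl, rel[span])
      }
    }
    carrier <- bandlimited_noise(nsamp, fs)
    sig[e, ] <- config$hg_amplitude * (1 + m) * carrier +
      pink_noise(nsamp, config$noise$pink_exponent, config$noise$pink_amplitude)
    if (config$noise$line_amplitude > 0) {
      sig[e, ] <- sig[e, ] +
        config$noise$line_amplitude * sin(2 * pi * 60 * (t_ms / 1000))
    }
  }
  rec <- ecog_recording(sig, fs, meta[, c("id", "participant", "hemisphere",
                                          "grid", "surface", "valid")])
  audio <- generate_audio(trials, config$sampling_rate_audio,
                          burst_duration_s = config$burst_duration_s,
                          duration_s = dur)
  gt <- list(
    electrodes = meta[, c("id", "participant", "hemisphere", "cluster",
                          "tuned_unit", "tuned_label", "effect")],
    trials = trials[, c("trial", "voice_onset")]
  )
  list(recording = rec, audio = audio, trials = trials, ground_truth = gt)
}

#' Generate a multi-participant study
#'
#' Runs [generate_session()] once per participant, deriving one sub-seed per
#' participant from `config$seed`, so the whole study is a deterministic
#' function of the configuration.
#'
#' @param config a [sim_config()].
#' @return named list of session lists, named "S1", "S2", ...
#' @export
generate_study <- function(config) {
  validate_sim_config(config)
  ids <- paste0("S", seq_len(config$n_participants))
  stats::setNames(lapply(seq_along(ids), function(i) {
    generate_session(config, ids[i], seed = config$seed + (i - 1L) * 1009L)
  }), ids)
}

#' Generate synthetic ERSP profiles with planted temporal clusters
#'
#' Builds trial-averaged ERSP time-courses directly, bypassing the raw
#' signal chain: each electrode is assigned a template (per the hemisphere
#' mixture or uniformly), its single-trial response is the template plus
#' Gaussian noise with per-timepoint sd `peak / snr`, and the returned
#' profile is the average over `n_trials` such trials — so the profile
#' noise scales as `peak / (snr * sqrt(n_trials))`, as it does for a real
#' event-related average. Useful as a fast, ground-truthed input surface
#' for the clustering stage.
#'
#' @param n_electrodes number of profiles.
#' @param templates landmark table (see [canonical_templates()]).
#' @param mixture template probabilities (defaults to uniform).
#' @param snr single-trial signal-to-noise ratio (template peak over noise
#'   sd); default 3.
#' @param n_trials trials averaged per profile (default 130).
#' @param time_ms time axis (ms); default -2000..995 in 20 ms steps.
#' @param peak_z template peak amplitude in z-units (default 3).
#' @return list with `profiles` (n x T matrix), `time_ms`, `cluster`
#'   (planted template per profile).
#' @export
generate_ersp_profiles <- function(n_electrodes,
                                   templates = canonical_templates(),
                                   mixture = NULL, snr = 3, n_trials = 130,
                                   time_ms = seq(-2000, 995, by = 20),
                                   peak_z = 3) {
  k <- nrow(templates)
  if (is.null(mixture)) mixture <- rep(1 / k, k)
  truth <- sample.int(k, n_electrodes, replace = TRUE, prob = mixture)
  profiles <- matrix(0, n_electrodes, length(time_ms))
  for (i in seq_len(n_electrodes)) {
    tpl <- template_trace(templates[truth[i], ], time_ms)
    tpl <- tpl / max(tpl) * peak_z
    noise_sd <- peak_z / snr / sqrt(n_trials)
    profiles[i, ] <- tpl + stats::rnorm(length(time_ms), sd = noise_sd)
  }
  list(profiles = profiles, time_ms = time_ms, cluster = truth)
}
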