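# Shared fixtures built in code: small epoch objects and correctness arrays
# with planted tuning, bypassing the raw-signal chain where a test targets
# a downstream stage. Tests set their own seeds before calling these.

stim_set <- generate_stimulus_set()

# hg_epochs-shaped object with unit-variance noise and a planted response
# template; `tuned` electrodes get amplitude x (1 + effect) on trials whose
# label for `unit` equals `label`.
make_test_epochs <- function(n_el, n_tr, time_ms = seq(-1000, 999, by = 25),
                             peak_z = 3, tuned = integer(0),
                             unit = "vowel", label = "i", effect = 0) {
  rows <- sample(rep(seq_len(12), ceiling(n_tr / 12)))[seq_len(n_tr)]
  syl <- stim_set$syllables[rows, ]
  trials <- data.frame(syllable = syl$syllable,
                       consonant_pair = syl$consonant_pair,
                       vowel = syl$vowel)
  tpl <- template_trace(canonical_templates()[4, ], time_ms)
  tpl <- tpl / max(tpl)
  arr <- array(stats::rnorm(n_el * n_tr * length(time_ms)),
               c(n_el, n_tr, length(time_ms)))
  ucol <- c(consonant = "consonant_pair", vowel = "vowel",
            syllable = "syllable")[unit]
  for (e in seq_len(n_el)) {
    for (tr in seq_len(n_tr)) {
      sc <- if (e %in% tuned && trials[[ucol]][tr] == label) 1 + effect else 1
      arr[e, tr, ] <- arr[e, tr, ] + peak_z * sc * tpl
    }
  }
  structure(list(power = arr, time_ms = time_ms, trials = trials,
                 sampling_rate = 1000 / diff(time_ms)[1],
                 electrode_meta = data.frame(id = sprintf("e%02d", seq_len(n_el))),
                 baseline = list(ms = 500, mode = "epoch_start")),
            class = "hg_epochs")
}

# trials x electrodes x 3-units correctness array from single-electrode
# decoding of a make_test_epochs session
make_correctness <- function(epochs, n_folds = 5) {
  fm <- extract_features(epochs, window = c(-1000, 1000))
  folds <- hgspeech:::make_folds(epochs$trials$syllable, n_folds)
  units <- c(consonant = "consonant_pair", vowel = "vowel",
             syllable = "syllable")
  n_el <- dim(epochs$power)[1]
  corr <- array(NA_integer_, c(nrow(epochs$trials), n_el, 3),
                dimnames = list(NULL, epochs$electrode_meta$id, names(units)))
  for (u in names(units)) {
    corr[, , u] <- single_electrode_classify(fm, epochs$trials[[units[u]]],
                                             folds = folds)
  }
  corr
}

# hg_series carrying a given amplitude matrix (electrodes x samples)
make_hg_series <- function(amplitude, fs, ids = NULL) {
  structure(list(amplitude = amplitude, sampling_rate = fs,
                 electrode_meta = data.frame(
                   id = ids %||% sprintf("e%02d", seq_len(nrow(amplitude))))),
            class = "hg_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
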