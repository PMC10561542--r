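# Audio conditioning: voice-onset detection and RMS envelope.

#' Detect voice onsets in an audio track
#'
#' Convolves a 20-ms rectangular kernel with the absolute value of the
#' audio, marks contiguous supra-threshold periods as voicing, and returns
#' the start of each voiced period, keeping only onsets more than
#' `min_gap_s` after the previously kept onset.
#'
#' @param audio numeric waveform.
#' @param sampling_rate sampling rate (Hz); taken from the waveform's
#'   `sampling_rate` attribute when missing.
#' @param threshold amplitude threshold on the smoothed |audio|; must be
#'   positive.
#' @param min_gap_s minimum gap (s) between successive onsets (default 0.3).
#' @param kernel_ms smoothing kernel duration (ms).
#' @return numeric vector of onset times in seconds, sorted ascending.
#' @export
detect_voice_onsets <- function(audio, sampling_rate = attr(audio, "sampling_rate"),
                                threshold, min_gap_s = 0.3, kernel_ms = 20) {
  if (!length(audio)) stop("audio is empty")
  if (is.null(sampling_rate) || sampling_rate <= 0) stop("invalid sampling rate")
  if (any(!is.finite(audio))) stop("audio contains non-finite samples")
  if (threshold <= 0) stop("threshold must be positive")
  k <- max(1L, round(kernel_ms / 1000 * sampling_rate))
  sm <- as.numeric(stats::filter(abs(audio), rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- 0
  above <- sm > threshold
  if (!any(above)) return(numeric(0))
  starts <- which(above & !c(FALSE, above[-length(above)]))
  times <- (starts - 1) / sampling_rate
  kept <- times[1]
  for (t in times[-1]) {
    if (t - kept[length(kept)] > min_gap_s) kept <- c(kept, t)
  }
  kept
}

#' RMS sound envelope
#'
#' Root-mean-square of the raw audio over consecutive non-overlapping
#' windows (50 ms by default), one value per complete window.
#'
#' @param audio numeric waveform.
#' @param sampling_rate sampling rate (Hz).
#' @param window_ms window length (ms).
#' @return non-negative numeric vector, one value per window.
#' @export
compute_audio_envelope <- function(audio, sampling_rate = attr(audio, "sampling_rate"),
                                   window_ms = 50) {
  if (!length(audio)) stop("audio is empty")
  if (is.null(sampling_rate) || sampling_rate <= 0) stop("invalid sampling rate")
  w <- max(1L, round(window_ms / 1000 * sampling_rate))
  nwin <- floor(length(audio) / w)
  if (nwin < 1L) stop("audio shorter than one envelope window")
  x2 <- audio[seq_len(nwin * w)]^2
  sqrt(colMeans(matrix(x2, nrow = w)))
}
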