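# Internal numerical helpers shared across the pipeline.

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Returns the complex analytic signal `x + i * H(x)` of a real vector, from
#' which the instantaneous amplitude envelope is `Mod(analytic_signal(x))`.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("signal too short for analytic transform")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' 1/f ("pink") noise by spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain with amplitude
#' proportional to f^(-exponent/2), giving a power spectrum ~ 1/f^exponent,
#' then rescaled to the requested standard deviation.
#'
#' @param n number of samples.
#' @param exponent spectral exponent (1 = classic pink noise).
#' @param sd target standard deviation of the output.
#' @return numeric vector of length `n`.
#' @keywords internal
pink_noise <- function(n, exponent = 1, sd = 1) {
  if (n < 2L) return(stats::rnorm(n, sd = sd))
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  freqs <- c(1, seq_len(n - 1L))          # avoid division by zero at DC
  shape <- freqs^(-exponent / 2)
  # keep conjugate symmetry by shaping magnitudes symmetrically
  half <- floor(n / 2L)
  shape <- c(shape[1L:(half + 1L)], rev(shape[2L:(n - half)]))
  x <- Re(stats::fft(X * shape[seq_len(n)], inverse = TRUE) / n)
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * sd / s
}

#' Band-limited Gaussian noise carrier
#'
#' White noise band-pass filtered to `band` (Hz) with a zero-phase
#' Butterworth filter and rescaled to unit standard deviation; used as the
#' carrier onto which simulated high-gamma amplitude modulation is imposed.
#'
#' @param n number of samples.
#' @param sampling_rate sampling rate in Hz.
#' @param band numeric length-2, passband in Hz.
#' @return numeric vector of length `n` with sd 1.
#' @keywords internal
bandlimited_noise <- function(n, sampling_rate, band = c(70, 150)) {
  ny <- sampling_rate / 2
  bf <- signal::butter(4, band / ny, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

#' Sample kurtosis (non-excess)
#' @keywords internal
sample_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(NA_real_)
  mean(x^4) / m2^2
}

# least-squares slope of y against an index axis measured in seconds
slope_per_second <- function(y, dt_s) {
  n <- length(y)
  if (n < 2L) return(NA_real_)
  t <- (seq_len(n) - 1) * dt_s
  stats::cov(t, y) / stats::var(t)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
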