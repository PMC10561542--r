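# Kalman-filter trend estimation and change-point detection for high-gamma
# power traces.
#
# The filter tracks a two-dimensional state X = [g, g_dot] (power and its
# trend) with a constant-velocity transition A = [[1,1],[0,1]] and an
# observation model H = [1, 0] (only the power is observed). A decay factor
# alpha = exp(-Delta / (delta * Fs)) shrinks the Kalman gain as evidence for
# the current trend accumulates, "freezing" the trend so that deviations
# from it (change points) can be flagged before the model is corrupted by
# data that no longer fits. On each detected change the filter is
# re-initialized at the change, with the empirical trend taken from 100 ms
# of data around it (10% past / 90% future) and the decay reset.

#' Trend-filter configuration
#'
#' @param delta_ms gain-decay time constant (ms); default 100.
#' @param tau scale (in samples) relating trend-noise to power-noise in the
#'   process covariance initialization Q = diag(v, v / tau^2) where v is the
#'   variance of the first-differenced baseline.
#' @param reinit_ms width (ms) of the window used to re-estimate the
#'   empirical trend at a change point.
#' @param reinit_past_frac fraction of the re-initialization window taken
#'   from before the change (default 0.1, the rest from the future).
#' @param conf_electrode one-sided confidence level of the per-electrode
#'   baseline value entering threshold calibration.
#' @param conf_global confidence level of the pooled (beta) distribution
#'   used for the shared threshold.
#' @return list of class `trend_config`.
#' @export
trend_config_default <- function(delta_ms = 100, tau = 10, reinit_ms = 100,
                                 reinit_past_frac = 0.1,
                                 conf_electrode = 0.95, conf_global = 0.99) {
  stopifnot(delta_ms > 0, tau > 0, reinit_ms > 0)
  structure(list(delta_ms = delta_ms, tau = tau, reinit_ms = reinit_ms,
                 reinit_past_frac = reinit_past_frac,
                 conf_electrode = conf_electrode, conf_global = conf_global),
            class = "trend_config")
}

#' Initialize the trend filter from a baseline segment
#'
#' X is initialized to [0, 0]; Q to the difference-stationary whitened
#' baseline variance, diag(var(diff(baseline)), var(diff(baseline))/tau^2);
#' P to Q; and the observation-noise variance R to the overall variance of
#' the baseline power. The step counter Delta starts at 0.
#'
#' @param baseline numeric baseline samples (>= 100 ms worth).
#' @param fs sampling rate (Hz).
#' @param config a [trend_config_default()].
#' @return list of class `trend_state` with elements `X`, `P`, `Q`, `R`,
#'   `H`, `delta_steps`, `fs`, `delta_ms`, `init_power`, `measured_trend`.
#' @export
init_trend_filter <- function(baseline, fs, config = trend_config_default()) {
  if (length(baseline) < round(0.1 * fs)) {
    stop("baseline must cover at least 100 ms")
  }
  v <- stats::var(baseline)
  if (!is.finite(v) || v == 0) stop("baseline variance is zero")
  vd <- stats::var(diff(baseline))
  Q <- diag(c(vd, vd / config$tau^2))
  structure(list(X = c(0, 0), P = Q, Q = Q, R = v, H = c(1, 0),
                 delta_steps = 0L, fs = fs, delta_ms = config$delta_ms,
                 init_power = 0, measured_trend = 0),
            class = "trend_state")
}

#' Kalman prediction step
#'
#' Propagates the state through the constant-velocity model:
#' g <- g + g_dot, g_dot unchanged; P <- A P A' + Q.
#'
#' @param state a `trend_state`.
#' @return the advanced `trend_state`.
#' @export
kalman_predict <- function(state) {
  A <- matrix(c(1, 0, 1, 1), 2, 2)   # column-major: [[1,1],[0,1]]
  state$X <- as.numeric(A %*% state$X)
  state$P <- A %*% state$P %*% t(A) + state$Q
  state
}

#' Kalman update step with gain decay
#'
#' Computes alpha = exp(-Delta / (delta * Fs)) from the steps since the last
#' (re-)initialization, the decayed gain K = alpha P H' / (H P H' + R), and
#' updates X <- X + K (z - H X). The measured trend component is refreshed
#' as (z - power at last initialization) / Delta, and Delta is incremented.
#'
#' @param state a `trend_state` that has been advanced by
#'   [kalman_predict()] this time step.
#' @param z observed power (z-units).
#' @return the updated `trend_state`; element `innovation` carries
#'   z - H X_pred for change testing.
#' @export
kalman_update <- function(state, z) {
  H <- state$H
  S <- as.numeric(H %*% state$P %*% H + state$R)
  if (S == 0) stop("degenerate innovation variance")
  alpha <- exp(-state$delta_steps / (state$delta_ms / 1000 * state$fs))
  K <- alpha * as.numeric(state$P %*% H) / S
  innov <- z - as.numeric(H %*% state$X)
  state$X <- state$X + K * innov
  state$P <- (diag(2) - K %*% t(H)) %*% state$P
  state$delta_steps <- state$delta_steps + 1L
  state$measured_trend <- (z - state$init_power) / max(state$delta_steps, 1L)
  state$innovation <- innov
  state
}

#' Calibrate the shared change threshold across electrodes
#'
#' Each electrode contributes a one-sided 95% confidence value of its
#' z-scored baseline power, sd * qnorm(0.95) (the Gaussian upper-tail
#' inverse of the Q-function). A beta distribution is fitted by the method
#' of moments to the pooled values (rescaled to (0, 1) by their maximum) and
#' its 99% quantile is returned as the single threshold shared by all
#' electrodes, a stricter pooled criterion that corrects for testing many
#' electrodes.
#'
#' @param baselines list of numeric vectors, one per electrode (z-scored
#'   single-trial baseline samples).
#' @param config a [trend_config_default()].
#' @return scalar threshold (z-units).
#' @export
calibrate_threshold <- function(baselines, config = trend_config_default()) {
  if (length(baselines) < 2L) stop("threshold pooling needs >= 2 electrodes")
  sds <- vapply(baselines, stats::sd, numeric(1))
  vals <- sds * stats::qnorm(config$conf_electrode)
  if (any(!is.finite(vals))) stop("non-finite baseline confidence values")
  if (max(vals) - min(vals) < 1e-12) return(vals[1])
  x <- vals / max(vals)
  m <- mean(x); v <- stats::var(x)
  a <- m * (m * (1 - m) / v - 1)
  b <- (1 - m) * (m * (1 - m) / v - 1)
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    warning("beta fit failed; falling back to the empirical quantile")
    return(unname(stats::quantile(vals, config$conf_global)))
  }
  max(vals) * stats::qbeta(config$conf_global, a, b)
}

#' Detect trend change points in a power trace
#'
#' Initializes the filter on the baseline segment of the trace, then runs
#' predict/update across the remaining samples. Whenever the absolute
#' innovation |z - H X_pred| exceeds `threshold`, a change point is
#' recorded and the filter is re-initialized at that time: the state takes
#' the current observation and the empirical trend fitted over `reinit_ms`
#' of data around the change (10% past, 90% future), P is recomputed from
#' the local signal (variance of the trailing window and of its first
#' differences), and the gain decay is reset. Segment slopes between
#' successive change points are fitted by least squares and reported per
#' second.
#'
#' @param trace numeric power trace (typically a trial-averaged ERSP).
#' @param time_ms time axis (ms relative to voice onset), same length.
#' @param baseline_window length-2 ms window of the baseline segment.
#' @param threshold global change threshold (z-units), from
#'   [calibrate_threshold()] or supplied directly.
#' @param config a [trend_config_default()].
#' @return object of class `trend_series`: list with `change_points`
#'   (data.frame: `time_ms`), `segments` (data.frame: `start_ms`, `end_ms`,
#'   `slope_per_s`, `level`), `responsive` (any change after baseline),
#'   `threshold`.
#' @export
detect_change_points <- function(trace, time_ms, baseline_window, threshold,
                                 config = trend_config_default()) {
  stopifnot(length(trace) == length(time_ms), threshold > 0)
  dt_ms <- stats::median(diff(time_ms))
  fs <- 1000 / dt_ms
  bl <- which(time_ms >= baseline_window[1] & time_ms < baseline_window[2])
  if (!length(bl)) stop("baseline window outside the trace")
  if (length(trace) < length(bl) + round(config$reinit_ms / dt_ms)) {
    stop("trace shorter than baseline + re-initialization window")
  }
  state <- init_trend_filter(trace[bl], fs, config)
  w <- max(2L, round(config$reinit_ms / dt_ms))
  n_past <- max(0L, round(config$reinit_past_frac * w))
  cp_idx <- integer(0)
  start_i <- max(bl) + 1L
  i <- start_i
  n <- length(trace)
  while (i <= n) {
    state <- kalman_predict(state)
    innov <- trace[i] - state$X[1]
    if (abs(innov) > threshold) {
      cp_idx <- c(cp_idx, i)
      lo <- max(1L, i - n_past)
      hi <- min(n, i + (w - n_past) - 1L)
      seg <- trace[lo:hi]
      slope_step <- if (length(seg) >= 2L) {
        stats::cov(seq_along(seg), seg) / stats::var(seq_along(seg))
      } else 0
      loc <- trace[max(1L, i - w + 1L):i]
      pv <- stats::var(loc)
      dv <- if (length(loc) >= 3L) stats::var(diff(loc)) else pv
      state$X <- c(trace[i], slope_step)
      state$P <- diag(c(max(pv, 1e-12), max(dv, 1e-12)))
      state$delta_steps <- 0L
      state$init_power <- trace[i]
      state$measured_trend <- 0
    } else {
      state <- kalman_update(state, trace[i])
    }
    i <- i + 1L
  }
  bounds <- c(start_i, cp_idx, n)
  segs <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                     slope_per_s = numeric(0), level = numeric(0))
  for (j in seq_len(length(bounds) - 1L)) {
    a <- bounds[j]; b <- bounds[j + 1L]
    if (b - a < 1L) next
    y <- trace[a:b]
    segs <- rbind(segs, data.frame(
      start_ms = time_ms[a], end_ms = time_ms[b],
      slope_per_s = slope_per_second(y, dt_ms / 1000),
      level = mean(y)))
  }
  structure(list(
    change_points = data.frame(time_ms = time_ms[cp_idx]),
    segments = segs,
    responsive = length(cp_idx) > 0L,
    threshold = threshold,
    baseline_window = baseline_window
  ), class = "trend_series")
}

#' Timing landmarks of a response time-course
#'
#' Derives the Table-of-landmarks description of a responsive trace:
#' `start` is the first post-baseline change point (deviation from the
#' baseline trend); `peak` is the time of maximum absolute power;
#' `end` is the first sustained return (>= 50 ms) of the trace into the
#' baseline 95% band after the peak, right-censored (Inf) when the response
#' is still elevated at the trace end; onset/offset slopes are least-squares
#' fits over the rising and falling segments, in units of 1/s.
#'
#' @param trace numeric trace (same scale used for the change analysis).
#' @param time_ms time axis in ms.
#' @param series the matching [detect_change_points()] result.
#' @return object of class `cluster_landmarks`: list with `start_ms`,
#'   `onset_slope`, `peak_ms`, `offset_slope`, `end_ms`, `censored`.
#' @export
extract_landmarks <- function(trace, time_ms, series) {
  stopifnot(inherits(series, "trend_series"))
  if (!series$responsive) stop("trace is not responsive; no landmarks")
  dt_ms <- stats::median(diff(time_ms))
  start_ms <- series$change_points$time_ms[1]
  after_start <- time_ms >= start_ms
  peak_i <- which(after_start)[which.max(abs(trace[after_start]))]
  peak_ms <- time_ms[peak_i]
  bl <- time_ms >= series$baseline_window[1] & time_ms < series$baseline_window[2]
  band <- mean(trace[bl]) + c(-1, 1) * 1.96 * stats::sd(trace[bl])
  inside <- trace >= band[1] & trace <= band[2]
  need <- max(1L, round(50 / dt_ms))
  end_ms <- Inf
  post <- which(time_ms > peak_ms)
  if (length(post) >= need) {
    run <- 0L
    for (i in post) {
      run <- if (inside[i]) run + 1L else 0L
      if (run >= need) { end_ms <- time_ms[i - need + 1L]; break }
    }
  }
  rise <- time_ms >= start_ms & time_ms <= peak_ms
  fall <- time_ms >= peak_ms & time_ms <= min(end_ms, max(time_ms))
  structure(list(
    start_ms = start_ms,
    onset_slope = slope_per_second(trace[rise], dt_ms / 1000),
    peak_ms = peak_ms,
    offset_slope = slope_per_second(trace[fall], dt_ms / 1000),
    end_ms = end_ms,
    censored = !is.finite(end_ms)
  ), class = "cluster_landmarks")
}

#' @export
print.cluster_landmarks <- function(x, ...) {
  cat(sprintf("start %.0f ms, onset %.2f/s, peak %.0f ms, offset %.2f/s, end %s\n",
              x$start_ms, x$onset_slope, x$peak_ms, x$offset_slope,
              if (x$censored) paste0("> ", "trace end") else sprintf("%.0f ms", x$end_ms)))
  invisible(x)
}
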