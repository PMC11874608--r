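# Kinematic scoring pipeline: raw two-channel position traces -> continuous
# relative phase -> proportion of time on target (PTT).

# wrap degrees to (-180, 180]
wrap_180 <- function(d) {
  w <- ((d + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

# unwrap a phase sequence in degrees
unwrap_deg <- function(p) {
  if (length(p) < 2) return(p)
  p[1] + c(0, cumsum(wrap_180(diff(p))))
}

# circular distance between folded phases (both in [0, 180])
folded_distance <- function(s, t) {
  pmin(abs(s - t), s + t, 360 - s - t)
}

#' Centre, low-pass filter, and differentiate a position trace
#'
#' Mean-centres the trace, applies a 2nd-order Butterworth low-pass filter
#' forward and backward (zero phase lag) with odd-reflection edge padding,
#' and computes velocity by central differences. Zero phase matters because
#' the whole pipeline exists to estimate phase.
#'
#' @param raw_position Numeric position trace, screen units.
#' @param sample_rate Samples/s.
#' @param cutoff Low-pass cut-off frequency, Hz (default 10). Must be below
#'   the Nyquist frequency.
#' @return An object of class `filtered_trajectory` with fields `position`,
#'   `velocity` (units/s), and `sample_rate`.
#' @export
preprocess_trajectory <- function(raw_position, sample_rate, cutoff = 10) {
  n <- length(raw_position)
  if (!is.numeric(raw_position) || !all(is.finite(raw_position))) {
    stop("raw_position must be finite numeric")
  }
  if (n < sample_rate) stop("need at least one second of data")
  if (cutoff >= sample_rate / 2) {
    stop("cutoff must be below the Nyquist frequency")
  }
  x <- raw_position - mean(raw_position)
  bf <- signal::butter(2, cutoff / (sample_rate / 2), type = "low")
  p <- min(n - 1, as.integer(round(sample_rate)))
  padded <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filtfilt(bf, padded)[(p + 1):(p + n)]
  v <- numeric(n)
  v[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) * sample_rate / 2
  v[1] <- (y[2] - y[1]) * sample_rate
  v[n] <- (y[n] - y[n - 1]) * sample_rate
  structure(list(position = y, velocity = v, sample_rate = sample_rate),
            class = "filtered_trajectory")
}

#' Continuous phase of one oscillating channel
#'
#' Computes the per-sample phase angle by the four-quadrant arctangent of
#' normalized position and velocity: position is scaled by the trial
#' amplitude (half the peak-to-peak range of the filtered trace) and
#' velocity by amplitude times `2 pi f`, with `f` taken from the dominant
#' spectral peak (falling back to `frequency_hint` when the spectrum is
#' degenerate). For `x(t) = A sin(2 pi f t + c)` the returned phase is
#' `360 f t + c` degrees, unwrapped.
#'
#' @param traj A [preprocess_trajectory()] result.
#' @param frequency_hint Fallback frequency, Hz.
#' @return Numeric vector of unwrapped phase, degrees, with the estimated
#'   `amplitude` and `frequency` attached as attributes.
#' @export
continuous_phase <- function(traj, frequency_hint = 1) {
  stopifnot(inherits(traj, "filtered_trajectory"))
  x <- traj$position
  n <- length(x)
  amp <- (max(x) - min(x)) / 2
  if (!is.finite(amp) || amp < 1e-8) {
    stop("degenerate trial: oscillation amplitude is near zero")
  }
  freq <- frequency_hint
  if (n >= 8) {
    spec <- Mod(stats::fft(x))[2:floor(n / 2)]
    k <- which.max(spec)
    if (length(k) == 1 && is.finite(spec[k]) && spec[k] > 0) {
      freq <- k * traj$sample_rate / n
    }
  }
  if (!is.finite(freq) || freq <= 0) freq <- frequency_hint
  omega <- 2 * pi * freq
  ph <- atan2(x / amp, traj$velocity / (amp * omega)) * 180 / pi
  structure(unwrap_deg(ph), amplitude = amp, frequency = freq)
}

#' Relative phase series from two phase sequences
#'
#' Per-sample difference `left - right`, wrapped to `(-180, 180]` and then
#' folded by absolute value to `[0, 180]`, so lead and lag are pooled (the
#' standard convention in the bimanual coordination literature).
#'
#' @param left,right Unwrapped phase sequences, degrees, equal length.
#' @param target_phase Target relative phase, degrees.
#' @param sample_rate Optional samples/s, carried as metadata.
#' @return An object of class `phase_series` with fields `relative_phase`
#'   (degrees in `[0, 180]`), `sample_rate`, `target_phase`.
#' @export
relative_phase_series <- function(left, right, target_phase,
                                  sample_rate = NULL) {
  if (length(left) != length(right)) {
    stop("left and right phase sequences must have equal length")
  }
  if (length(left) < 2) stop("need at least two samples")
  structure(list(relative_phase = abs(wrap_180(left - right)),
                 sample_rate = sample_rate,
                 target_phase = target_phase),
            class = "phase_series")
}

#' Proportion of time on target
#'
#' Fraction of samples whose circular distance (on the folded `[0, 180]`
#' scale) to the target phase is at most `bandwidth`, inclusive. The default
#' 20-degree bandwidth gives the standard PTT20 performance measure; the
#' 10-degree alternative supports bias analyses.
#'
#' @param series A [relative_phase_series()] result.
#' @param bandwidth Half-width of the on-target band, degrees, `> 0`.
#' @return An object of class `trial_score` with fields `ptt` (in `[0, 1]`),
#'   `bandwidth` and `target_phase`.
#' @examples
#' s <- relative_phase_series(rep(0, 10), rep(-90, 10), target_phase = 90)
#' ptt(s)$ptt # 1
#' @export
ptt <- function(series, bandwidth = 20) {
  stopifnot(inherits(series, "phase_series"))
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be positive")
  }
  if (length(series$relative_phase) == 0) stop("empty phase series")
  d <- folded_distance(series$relative_phase, series$target_phase)
  structure(list(ptt = mean(d <= bandwidth), bandwidth = bandwidth,
                 target_phase = series$target_phase),
            class = "trial_score")
}

#' @export
print.trial_score <- function(x, ...) {
  cat(sprintf("<trial_score> PTT%g = %.3f (target %g deg)\n",
              x$bandwidth, x$ptt, x$target_phase))
  invisible(x)
}

#' Score one trial end to end
#'
#' Composition of the full pipeline: [preprocess_trajectory()] on both
#' channels, [continuous_phase()], [relative_phase_series()], [ptt()].
#' Deterministic for a fixed input.
#'
#' @param trial A [trial_time_series()].
#' @param bandwidth Scoring bandwidth, degrees (default 20).
#' @param cutoff Filter cut-off, Hz.
#' @param frequency_hint Fallback movement frequency, Hz.
#' @param trim Seconds to drop from the start of the trial (default 0).
#' @return A `trial_score`.
#' @export
score_trial <- function(trial, bandwidth = 20, cutoff = 10,
                        frequency_hint = 1, trim = 0) {
  stopifnot(inherits(trial, "trial_time_series"))
  keep <- trial$time >= trial$time[1] + trim
  fs <- trial$sample_rate
  lt <- preprocess_trajectory(trial$left_position[keep], fs, cutoff)
  rt <- preprocess_trajectory(trial$right_position[keep], fs, cutoff)
  pl <- continuous_phase(lt, frequency_hint)
  pr <- continuous_phase(rt, frequency_hint)
  s <- relative_phase_series(pl, pr, trial$target_phase, fs)
  ptt(s, bandwidth)
}
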