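# Instantaneous phase extraction and the rate of change of the pairwise
# phase difference: the front half of the analysis pipeline.

#' Analytic signal of a real time series
#'
#' Computes the analytic signal `x + i H[x]` where `H` is the Hilbert
#' transform, via the standard frequency-domain construction: the FFT of
#' the signal with negative frequencies zeroed and positive frequencies
#' doubled.
#'
#' @param x Numeric vector, a uniformly sampled real signal.
#' @return Complex vector of the same length.
#' @seealso [analytic_phase()]
#' @export
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("signal too short for the analytic signal (need length >= 4)")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a signal
#'
#' The wrapped instantaneous phase, `Arg` of the analytic signal, in
#' `[-pi, pi]` per sample. A constant (or all-zero) signal has no defined
#' phase and raises an error.
#'
#' @param x Numeric vector, a uniformly sampled real signal of length >= 4.
#' @return Numeric vector of wrapped phases in radians.
#' @examples
#' ph <- analytic_phase(cos(2 * pi * 5 * (0:599) / 600))
#' range(ph)  # within [-pi, pi]
#' @export
analytic_phase <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("degenerate signal: length < 4")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  if (sd(x) == 0) stop("degenerate signal: constant input has no phase")
  Arg(analytic_signal(x))
}

#' Unwrap a wrapped phase series
#'
#' Removes the sawtooth discontinuities of a wrapped phase: wherever the
#' sample-to-sample jump exceeds `pi` in magnitude a multiple of `2*pi` is
#' added so that successive differences lie in `(-pi, pi]`. The first value
#' is preserved, so wrapping the result back recovers the input.
#'
#' @param phase Numeric vector of phases in radians.
#' @return Numeric vector, the unwrapped (unbounded) phase.
#' @export
unwrap_phase <- function(phase) {
  phase <- as.numeric(phase)
  if (length(phase) < 2L) return(phase)
  signal::unwrap(phase)
}

# Wrap angles back into (-pi, pi].
wrap_phase <- function(phase) {
  w <- (phase + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Unwrapped phase difference between two signals
#'
#' Phases are extracted per signal with [analytic_phase()], unwrapped
#' separately, and subtracted. This is the production path; the joint
#' arctangent form (one `atan2` of the cross terms of the two analytic
#' signals) is available as a cross-check via `method = "arctan"`, and
#' agrees with the separate-unwrap form modulo `2*pi`.
#'
#' @param s1,s2 Numeric vectors of equal length: the two signals.
#' @param method `"unwrap"` (default, separate unwrapping) or `"arctan"`
#'   (joint arctangent of the analytic cross terms, unwrapped afterwards).
#' @return Numeric vector of the unwrapped phase difference in radians.
#' @examples
#' t <- (0:999) / 100
#' d <- phase_difference(cos(2 * pi * t), cos(2 * pi * t - pi / 2))
#' mean(d[100:900])  # close to pi/2
#' @export
phase_difference <- function(s1, s2, method = c("unwrap", "arctan")) {
  method <- match.arg(method)
  s1 <- as.numeric(s1); s2 <- as.numeric(s2)
  if (length(s1) != length(s2))
    stop("signals must have equal length (got ", length(s1), " and ", length(s2), ")")
  if (method == "unwrap") {
    p1 <- unwrap_phase(analytic_phase(s1))
    p2 <- unwrap_phase(analytic_phase(s2))
    p1 - p2
  } else {
    a1 <- analytic_signal(s1); a2 <- analytic_signal(s2)
    h1 <- Im(a1); h2 <- Im(a2)
    unwrap_phase(atan2(h1 * s2 - s1 * h2, s1 * s2 + h1 * h2))
  }
}

#' Rate of change of a phase difference
#'
#' First difference of consecutive samples: the series whose long-range
#' temporal correlations mark criticality in this framework. Its cumulative
#' sum recovers the phase difference minus its first value.
#'
#' @param diff_phase Numeric vector, an unwrapped phase difference.
#' @return Numeric vector of length `length(diff_phase) - 1`, in radians
#'   per sample step.
#' @export
rate_of_change <- function(diff_phase) {
  diff_phase <- as.numeric(diff_phase)
  if (length(diff_phase) < 2L) stop("need at least 2 samples")
  diff(diff_phase)
}

#' Zero-phase bandpass filter
#'
#' Forward-backward (zero-phase) 2nd-order Butterworth bandpass, i.e. 4
#' effective poles per band edge, specified by its half-power corners.
#' Zero-phase filtering preserves the phase relationships the rest of the
#' pipeline depends on.
#'
#' @param x Numeric vector, the signal.
#' @param fs Sampling rate in Hz.
#' @param low_hz,high_hz Band corners in Hz; requires
#'   `0 < low_hz < high_hz < fs/2`.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' fs <- 512
#' tone <- sin(2 * pi * 20 * (0:(4 * fs - 1)) / fs)
#' filt <- bandpass(tone, fs, 15.5, 27.5)  # in-band: amplitude preserved
#' @export
bandpass <- function(x, fs, low_hz, high_hz) {
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2))
    stop("invalid band: need 0 < low < high < fs/2")
  b <- signal::butter(2, c(low_hz, high_hz) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(b, as.numeric(x)))
}

#' Trim edge samples symmetrically
#'
#' The analytic signal is distorted near the edges of a finite record.
#' No samples are trimmed by default anywhere in the pipeline (long series
#' dilute the artifact); this helper supports an optional per-edge trim.
#'
#' @param x Numeric vector.
#' @param trim Number of samples to drop from each end.
#' @return Numeric vector of length `length(x) - 2 * trim`.
#' @export
trim_edges <- function(x, trim = 0L) {
  trim <- as.integer(trim)
  if (trim < 0L) stop("trim must be >= 0")
  if (trim == 0L) return(x)
  n <- length(x)
  if (2L * trim >= n) stop("trim removes the whole series")
  x[(trim + 1L):(n - trim)]
}
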