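#' Denoise an inertial channel
#'
#' Two-stage noise removal applied to every raw accelerometer and gyroscope
#' axis before any signal derivation: a width-3 median filter (suppresses
#' isolated spike impulses) followed by a third-order Butterworth low-pass
#' at 20 Hz, applied forward-backward (zero phase) so no group delay shifts
#' the signal relative to window boundaries.
#'
#' The minimum accepted length is 12 samples (four filter lengths of the
#' third-order stage), below which the forward-backward pass is not
#' well-defined.
#'
#' @param x numeric vector or n x 3 matrix (one channel per column).
#' @param sample_rate sampling rate in Hz; must exceed twice `cutoff`.
#' @param cutoff low-pass cutoff in Hz (default 20).
#' @param order Butterworth order (default 3).
#' @param median_k odd median-filter kernel width (default 3).
#' @return Filtered data with the same shape as `x`.
#' @export
denoise <- function(x, sample_rate, cutoff = 20, order = 3, median_k = 3) {
  if (sample_rate <= 2 * cutoff) {
    stop_belt(sprintf(
      "sample_rate (%g Hz) must exceed twice the %g Hz cutoff (Nyquist)",
      sample_rate, cutoff))
  }
  apply_channelwise(x, "denoise", function(v) {
    assert_finite(v, "denoise input")
    if (length(v) < 12) {
      stop_belt("denoise needs at least 12 samples")
    }
    v <- runmed(v, median_k, endrule = "keep")
    lowpass_zerophase(v, sample_rate, cutoff, order)
  })
}

#' Separate gravity and body-motion acceleration
#'
#' Splits denoised acceleration into a slow gravity component (third-order
#' zero-phase Butterworth low-pass, 0.3 Hz cutoff) and the body-motion
#' remainder. The two components sum back to the input exactly, per sample
#' and axis, because the body part is defined as input minus gravity.
#'
#' @param acc numeric vector or n x 3 matrix of denoised acceleration (g).
#' @param sample_rate sampling rate in Hz.
#' @param cutoff gravity cutoff in Hz (default 0.3).
#' @param order Butterworth order (default 3).
#' @return List with elements `gravity` and `body`, each shaped like `acc`.
#' @export
separate_gravity <- function(acc, sample_rate, cutoff = 0.3, order = 3) {
  gravity <- apply_channelwise(acc, "separate_gravity", function(v) {
    assert_finite(v, "separate_gravity input")
    if (length(v) < 12) {
      stop_belt("separate_gravity needs at least 12 samples")
    }
    lowpass_zerophase(v, sample_rate, cutoff, order)
  })
  list(gravity = gravity, body = acc - gravity)
}

#' Discrete time derivative (jerk)
#'
#' Differentiates a channel with central differences in the interior and
#' one-sided differences at the two ends, so the output keeps the input
#' length and stays sample-aligned with every other derived channel.
#' Applied to body acceleration this yields the jerk signal; applied to
#' angular speed it yields angular acceleration.
#'
#' @param x numeric vector or n x 3 matrix.
#' @param sample_rate sampling rate in Hz (the derivative is per second).
#' @return Derivative with the same shape as `x`.
#' @export
jerk <- function(x, sample_rate) {
  apply_channelwise(x, "jerk", function(v) {
    n <- length(v)
    if (n < 2) stop_belt("jerk needs at least 2 samples")
    d <- numeric(n)
    if (n > 2) {
      d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
    }
    d[1] <- v[2] - v[1]
    d[n] <- v[n] - v[n - 1]
    d * sample_rate
  })
}

#' Euclidean magnitude of a tri-axial channel
#'
#' @param xyz numeric n x 3 matrix.
#' @return Non-negative numeric vector of per-sample magnitudes
#'   `sqrt(x^2 + y^2 + z^2)`.
#' @export
magnitude <- function(xyz) {
  xyz <- as_xyz(xyz, "magnitude input")
  sqrt(rowSums(xyz^2))
}

#' One-sided magnitude spectrum of a window
#'
#' FFT convention frozen for reproducible feature values: for a
#' power-of-two window of length N the function returns the magnitude of
#' the one-sided spectrum, `Mod(fft(x))[1:(N/2 + 1)] / N` — N/2 + 1 bins
#' from DC to Nyquist, normalised by the window length, no taper. For the
#' default 128-sample window this is 65 bins at a 0.78125 Hz spacing
#' (100 Hz sampling).
#'
#' @param x numeric vector whose length is a power of two.
#' @return Non-negative numeric vector of length `length(x)/2 + 1`.
#' @export
to_frequency <- function(x) {
  n <- length(x)
  if (n < 2 || bitwAnd(n, n - 1L) != 0) {
    stop_belt(sprintf(
      "to_frequency requires a power-of-two window length, got %d", n))
  }
  Mod(fft(x))[1:(n / 2 + 1)] / n
}

# Shared zero-phase Butterworth low-pass. The forward-backward pass is run
# on an odd-reflection-padded copy (pad spanning ~6 filter time constants,
# capped at the signal length) so edge transients decay inside the padding:
# constants pass through exactly and the gravity estimate is stable from
# the first sample.
lowpass_zerophase <- function(v, sample_rate, cutoff, order) {
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  n <- length(v)
  npad <- min(n - 1, ceiling(6 * sample_rate / cutoff))
  left <- 2 * v[1] - v[(npad + 1):2]
  right <- 2 * v[n] - v[(n - 1):(n - npad)]
  out <- signal::filtfilt(bf, c(left, v, right))
  out[(npad + 1):(npad + n)]
}

apply_channelwise <- function(x, op, f) {
  if (is.matrix(x)) {
    out <- apply(x, 2, f)
    if (!is.matrix(out)) out <- matrix(out, ncol = ncol(x))
    colnames(out) <- colnames(x)
    out
  } else if (is.numeric(x)) {
    f(x)
  } else {
    stop_belt(sprintf("%s expects a numeric vector or matrix", op))
  }
}
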