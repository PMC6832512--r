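#' Window start offsets for sliding-window analysis
#'
#' Enumerates the 0-based sample offsets of fully contained analysis
#' windows: starts at 0, advances by `window * (1 - overlap)` samples, and
#' drops any trailing partial window. The defaults (128 samples, 50 %
#' overlap) give the 1.28 s windows used throughout the pipeline at 100 Hz.
#'
#' @param length recording length in samples.
#' @param window window length in samples (default 128).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return Integer vector of 0-based window start offsets (empty when the
#'   recording is shorter than one window).
#' @examples
#' make_windows(320) # 0, 64, 128, 192
#' @export
make_windows <- function(length, window = 128L, overlap = 0.5) {
  window <- as.integer(window)
  if (window <= 0) stop_belt("window must be positive")
  if (overlap < 0 || overlap >= 1) stop_belt("overlap must be in [0, 1)")
  step <- as.integer(round(window * (1 - overlap)))
  if (step <= 0) stop_belt("overlap too large: step rounds to zero samples")
  if (length < window) return(integer(0))
  seq.int(0L, as.integer(length) - window, by = step)
}

# The 17 channel names of the derived signal set, in the frozen order.
# t* = time domain (10), f* = frequency domain (7). "Gyro" is body angular
# speed, "GyroJerk" body angular acceleration.
TIME_CHANNELS <- c(
  "tBodyAcc", "tGravityAcc", "tBodyAccJerk", "tBodyGyro", "tBodyGyroJerk",
  "tBodyAccMag", "tGravityAccMag", "tBodyAccJerkMag", "tBodyGyroMag",
  "tBodyGyroJerkMag"
)
FREQ_CHANNELS <- c(
  "fBodyAcc", "fBodyAccJerk", "fBodyGyro",
  "fBodyAccMag", "fBodyAccJerkMag", "fBodyGyroMag", "fBodyGyroJerkMag"
)

#' Names of the 17 derived signal channels
#'
#' Ten time-domain channels (body/gravity acceleration, body jerk, angular
#' speed, angular acceleration, and their magnitudes) and the seven
#' frequency-domain channels (the body acceleration, jerk and angular-speed
#' tri-axial signals plus the four body magnitude signals; the gravity
#' channels and tri-axial angular acceleration stay time-domain only).
#'
#' @param domain `"all"`, `"time"` or `"frequency"`.
#' @return Character vector of channel names.
#' @export
signal_channels <- function(domain = c("all", "time", "frequency")) {
  switch(match.arg(domain),
         all = c(TIME_CHANNELS, FREQ_CHANNELS),
         time = TIME_CHANNELS,
         frequency = FREQ_CHANNELS)
}

#' Derive the 17-channel signal set from a raw recording
#'
#' Runs the full pre-processing chain on a raw recording: per-axis
#' denoising (median + 20 Hz third-order Butterworth, zero phase), gravity /
#' body separation at 0.3 Hz, differentiation of body acceleration (jerk)
#' and angular speed (angular acceleration), Euclidean magnitudes, and the
#' per-window one-sided FFT of the seven frequency-domain channels.
#'
#' Time-domain channels keep the full recording length. Frequency-domain
#' channels are stored per analysis window (the FFT is taken per 128-sample
#' window, matching how the features consume them): tri-axial channels as
#' `n_windows x n_bins x 3` arrays, magnitudes as `n_windows x n_bins`
#' matrices, with the window start offsets in `$window_starts`.
#'
#' @param rec an [imu_recording()].
#' @param window analysis window length in samples (default 128; must be a
#'   power of two for the FFT).
#' @param overlap fractional window overlap (default 0.5).
#' @return A `belt_signals` object: list of the 17 channels plus
#'   `sample_rate`, `window`, `window_starts`, `n_samples`, `labels`.
#' @export
derive_signals <- function(rec, window = 128L, overlap = 0.5) {
  if (!inherits(rec, "imu_recording")) {
    stop_belt("derive_signals expects an imu_recording")
  }
  fs <- rec$sample_rate
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop_belt(sprintf("derive_signals failed at stage '%s': %s",
                        what, conditionMessage(e)))
    })
  }

  acc_d <- stage("denoise acc", denoise(rec$acc, fs))
  gyro_d <- stage("denoise gyro", denoise(rec$gyro, fs))
  sep <- stage("gravity separation", separate_gravity(acc_d, fs))

  ch <- list()
  ch$tBodyAcc <- sep$body
  ch$tGravityAcc <- sep$gravity
  ch$tBodyAccJerk <- stage("jerk", jerk(sep$body, fs))
  ch$tBodyGyro <- gyro_d
  ch$tBodyGyroJerk <- stage("angular acceleration", jerk(gyro_d, fs))
  ch$tBodyAccMag <- magnitude(ch$tBodyAcc)
  ch$tGravityAccMag <- magnitude(ch$tGravityAcc)
  ch$tBodyAccJerkMag <- magnitude(ch$tBodyAccJerk)
  ch$tBodyGyroMag <- magnitude(ch$tBodyGyro)
  ch$tBodyGyroJerkMag <- magnitude(ch$tBodyGyroJerk)

  starts <- make_windows(n_samples(rec), window, overlap)
  nbin <- window / 2 + 1
  spectrum_of <- function(x) {
    if (is.matrix(x)) {
      out <- array(0, dim = c(length(starts), nbin, 3),
                   dimnames = list(NULL, NULL, c("X", "Y", "Z")))
      for (w in seq_along(starts)) {
        idx <- (starts[w] + 1):(starts[w] + window)
        for (a in 1:3) out[w, , a] <- to_frequency(x[idx, a])
      }
      out
    } else {
      out <- matrix(0, length(starts), nbin)
      for (w in seq_along(starts)) {
        idx <- (starts[w] + 1):(starts[w] + window)
        out[w, ] <- to_frequency(x[idx])
      }
      out
    }
  }
  fft_parent <- c(
    fBodyAcc = "tBodyAcc", fBodyAccJerk = "tBodyAccJerk",
    fBodyGyro = "tBodyGyro", fBodyAccMag = "tBodyAccMag",
    fBodyAccJerkMag = "tBodyAccJerkMag", fBodyGyroMag = "tBodyGyroMag",
    fBodyGyroJerkMag = "tBodyGyroJerkMag"
  )
  for (fname in names(fft_parent)) {
    ch[[fname]] <- stage(paste("FFT", fname), spectrum_of(ch[[fft_parent[fname]]]))
  }

  structure(
    c(ch, list(sample_rate = fs, window = as.integer(window),
               window_starts = starts, n_samples = n_samples(rec),
               labels = rec$labels)),
    class = "belt_signals"
  )
}

#' @export
print.belt_signals <- function(x, ...) {
  cat(sprintf("<belt_signals> %d samples @ %g Hz, %d windows of %d samples\n",
              x$n_samples, x$sample_rate, length(x$window_starts), x$window))
  cat(sprintf("  channels: %d time + %d frequency\n",
              length(TIME_CHANNELS), length(FREQ_CHANNELS)))
  invisible(x)
}
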