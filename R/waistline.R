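#' Magnetometer trace container
#'
#' Scalar magnetic-field time series recorded at the buckle while the belt
#' is inserted; each tooth of the 0.6 cm-pitch sawtooth belt surface drives
#' one oscillation of the pivoting blade and hence one peak cycle.
#'
#' @param values finite numeric vector.
#' @param sample_rate sampling rate in Hz.
#' @return A `mag_trace` object.
#' @export
mag_trace <- function(values, sample_rate = 100) {
  values <- as.numeric(values)
  if (length(values) < 1) stop_belt("trace must contain at least one sample")
  assert_finite(values, "magnetometer trace")
  if (sample_rate <= 0) stop_belt("sample_rate must be positive")
  structure(list(values = values, sample_rate = sample_rate),
            class = "mag_trace")
}

#' Count blade oscillation cycles in a magnetometer trace
#'
#' Schmitt-trigger (hysteresis) cycle counter: the trace is lightly
#' smoothed, linearly detrended against baseline drift and rescaled to its
#' robust amplitude range; one cycle is counted each time the signal
#' crosses above the `high` level after having been below the `low` level.
#' Because both levels are relative to the trace's own amplitude the count
#' is invariant to amplitude scaling, and noise smaller than the
#' `high - low` hysteresis band cannot double-count a cycle. A flat trace
#' has no amplitude range and counts zero.
#'
#' @param trace a [mag_trace()] or numeric vector.
#' @param high,low hysteresis levels as fractions of the amplitude range
#'   (defaults 0.6 and 0.4).
#' @param smooth odd moving-average width in samples (default 5; 1
#'   disables).
#' @return Integer cycle count.
#' @export
count_peaks <- function(trace, high = 0.6, low = 0.4, smooth = 5) {
  x <- if (inherits(trace, "mag_trace")) trace$values else as.numeric(trace)
  assert_finite(x, "magnetometer trace")
  if (!(low < high && low > 0 && high < 1)) {
    stop_belt("need 0 < low < high < 1")
  }
  n <- length(x)
  if (n < 3) return(0L)
  if (smooth > 1) {
    k <- min(as.integer(smooth), n)
    if (k %% 2 == 0) k <- k - 1L
    if (k > 1) x <- stats::filter(x, rep(1 / k, k), sides = 2)
    x <- as.numeric(x)
    x <- x[!is.na(x)]
    n <- length(x)
  }
  # remove linear baseline drift
  t0 <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t0), x)
  x <- fit$residuals + mean(x)
  r <- quantile(x, c(0.01, 0.99), names = FALSE)
  if (r[2] - r[1] <= 0) return(0L)
  z <- (x - r[1]) / (r[2] - r[1])
  count <- 0L
  armed <- z[1] < high
  for (i in seq_len(n)) {
    if (armed && z[i] > high) {
      count <- count + 1L
      armed <- FALSE
    } else if (!armed && z[i] < low) {
      armed <- TRUE
    }
  }
  count
}

#' Insertion distance from a cycle count
#'
#' One counted cycle per sawtooth tooth, so insertion distance is
#' `peak_count * pitch_cm`. The 0.6 cm default pitch is the tooth spacing
#' of the modified belt and sets the method's distance resolution.
#'
#' @param peak_count non-negative integer cycle count.
#' @param pitch_cm tooth pitch in cm (default 0.6).
#' @return Insertion distance in cm.
#' @export
insertion_distance <- function(peak_count, pitch_cm = 0.6) {
  if (peak_count < 0) stop_belt("peak_count must be non-negative")
  if (pitch_cm <= 0) stop_belt("pitch_cm must be positive")
  peak_count * pitch_cm
}

#' Waistline from belt length and insertion distance
#'
#' The waistline (inner length of the circle the belt forms) is the known
#' total belt length minus the distance inserted into the buckle, minus a
#' per-belt calibration offset absorbing the buckle geometry; floored at 0.
#'
#' @param belt_length_cm total belt length in cm.
#' @param insertion_cm insertion distance in cm, within
#'   `[0, belt_length_cm]`.
#' @param offset_cm per-belt calibration constant in cm (default 0).
#' @return Waistline in cm.
#' @export
waistline_from_insertion <- function(belt_length_cm, insertion_cm,
                                     offset_cm = 0) {
  if (insertion_cm < 0 || insertion_cm > belt_length_cm) {
    stop_belt("insertion distance must lie within [0, belt length]")
  }
  max(belt_length_cm - insertion_cm - offset_cm, 0)
}

#' Belt configuration
#'
#' @param belt_length_cm total belt length in cm.
#' @param pitch_cm sawtooth pitch in cm (default 0.6).
#' @param offset_cm per-belt calibration offset in cm (default 0).
#' @param high,low,smooth peak-detector settings, see [count_peaks()].
#' @return A `belt_config` list.
#' @export
belt_config <- function(belt_length_cm, pitch_cm = 0.6, offset_cm = 0,
                        high = 0.6, low = 0.4, smooth = 5) {
  if (belt_length_cm <= 0) stop_belt("belt_length_cm must be positive")
  if (pitch_cm <= 0) stop_belt("pitch_cm must be positive")
  structure(list(belt_length_cm = belt_length_cm, pitch_cm = pitch_cm,
                 offset_cm = offset_cm, high = high, low = low,
                 smooth = smooth),
            class = "belt_config")
}

#' Estimate waistline from a magnetometer insertion trace
#'
#' Composition of [count_peaks()], [insertion_distance()] and
#' [waistline_from_insertion()]. When the true insertion distance is
#' supplied (evaluation runs), absolute and relative errors are attached.
#'
#' @param trace a [mag_trace()] or numeric vector.
#' @param config a [belt_config()].
#' @param truth_cm optional true insertion distance in cm.
#' @return A `waistline_estimate`: `peak_count`, `insertion_cm`,
#'   `waistline_cm`, `pitch_cm`, and when `truth_cm` is given,
#'   `abs_error_cm` and `rel_error` (fraction).
#' @export
estimate_waistline <- function(trace, config, truth_cm = NULL) {
  if (!inherits(config, "belt_config")) {
    stop_belt("config must be a belt_config")
  }
  count <- count_peaks(trace, high = config$high, low = config$low,
                       smooth = config$smooth)
  insertion <- insertion_distance(count, config$pitch_cm)
  est <- list(
    peak_count = count,
    insertion_cm = insertion,
    waistline_cm = waistline_from_insertion(config$belt_length_cm, insertion,
                                            config$offset_cm),
    pitch_cm = config$pitch_cm
  )
  if (!is.null(truth_cm)) {
    est$abs_error_cm <- abs(insertion - truth_cm)
    est$rel_error <- if (truth_cm > 0) est$abs_error_cm / truth_cm else NA_real_
  }
  structure(est, class = "waistline_estimate")
}

#' @export
print.waistline_estimate <- function(x, ...) {
  cat(sprintf("<waistline_estimate> %d cycles -> insertion %.1f cm, waistline %.1f cm\n",
              x$peak_count, x$insertion_cm, x$waistline_cm))
  if (!is.null(x$abs_error_cm)) {
    cat(sprintf("  vs truth: absolute error %.2f cm (%.1f%%)\n",
                x$abs_error_cm, 100 * x$rel_error))
  }
  invisible(x)
}
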