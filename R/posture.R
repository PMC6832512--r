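#' Attitude angles from an acceleration vector
#'
#' Recovers the buckle's attitude from the gravity direction measured by
#' the accelerometer:
#' \deqn{\theta = \arctan\frac{Acc_X}{\sqrt{Acc_Y^2 + Acc_Z^2}}, \quad
#'       \psi = \arctan\frac{Acc_Y}{\sqrt{Acc_X^2 + Acc_Z^2}}, \quad
#'       \phi = \arctan\frac{\sqrt{Acc_X^2 + Acc_Y^2}}{|Acc_Z|}}
#' all in degrees. `theta` and `psi` are the X- and Y-axis rotations in
#' `[-90, 90]`; `phi`, the Z-axis rotation, is a ratio of magnitudes and
#' lies in `[0, 90]`, reaching 90 exactly when `Acc_Z = 0`. The angles are
#' scale-invariant, so the input does not need to be normalised to 1 g.
#'
#' @param acc numeric length-3 acceleration vector (g), or an n x 3 matrix
#'   for a per-row vectorised result. Must not be the zero vector (free
#'   fall leaves the attitude undefined).
#' @return For a vector input, a `posture_angles` object (named numeric:
#'   `theta`, `psi`, `phi`, degrees); for a matrix, a data frame with those
#'   columns.
#' @examples
#' attitude_angles(c(1, 0, 1) / sqrt(2)) # theta 45, psi 0, phi 45
#' @export
attitude_angles <- function(acc) {
  if (is.matrix(acc)) {
    acc <- as_xyz(acc, "acc")
    if (any(rowSums(acc^2) == 0)) {
      stop_belt("attitude undefined for a zero acceleration vector")
    }
    deg <- 180 / pi
    return(data.frame(
      theta = atan2(acc[, 1], sqrt(acc[, 2]^2 + acc[, 3]^2)) * deg,
      psi = atan2(acc[, 2], sqrt(acc[, 1]^2 + acc[, 3]^2)) * deg,
      phi = atan2(sqrt(acc[, 1]^2 + acc[, 2]^2), abs(acc[, 3])) * deg
    ))
  }
  if (length(acc) != 3 || !all(is.finite(acc))) {
    stop_belt("acc must be a finite length-3 vector")
  }
  if (all(acc == 0)) {
    stop_belt("attitude undefined for a zero acceleration vector")
  }
  deg <- 180 / pi
  structure(
    c(theta = atan2(acc[1], sqrt(acc[2]^2 + acc[3]^2)) * deg,
      psi = atan2(acc[2], sqrt(acc[1]^2 + acc[3]^2)) * deg,
      phi = atan2(sqrt(acc[1]^2 + acc[2]^2), abs(acc[3])) * deg),
    class = "posture_angles"
  )
}

#' @export
print.posture_angles <- function(x, ...) {
  cat(sprintf("<posture_angles> theta %.1f deg, psi %.1f deg, phi %.1f deg\n",
              x[["theta"]], x[["psi"]], x[["phi"]]))
  invisible(x)
}

#' Good-posture policy
#'
#' The two-policy rule for a good sitting posture: (a) left/right tilt
#' horizontal — `|psi|` within `psi_tolerance` of 0; (b) front/rear tilt
#' almost vertical — `phi` within `[phi_min, phi_max]`. The published
#' policy gives the targets (`psi` near 0, `phi` 80-90 degrees) without
#' exact cutoffs; the tolerances here are explicit, configurable choices.
#'
#' @param psi_tolerance allowed `|psi|` in degrees (default 10).
#' @param phi_min,phi_max allowed `phi` band in degrees (defaults 80, 90).
#' @return A `posture_rule` object.
#' @export
posture_rule <- function(psi_tolerance = 10, phi_min = 80, phi_max = 90) {
  if (psi_tolerance < 0) stop_belt("psi_tolerance must be non-negative")
  if (!(phi_min >= 0 && phi_min <= phi_max && phi_max <= 90)) {
    stop_belt("need 0 <= phi_min <= phi_max <= 90")
  }
  structure(list(psi_tolerance = psi_tolerance, phi_min = phi_min,
                 phi_max = phi_max),
            class = "posture_rule")
}

#' Classify posture as good or poor
#'
#' @param angles a `posture_angles` object, or a data frame with `psi` and
#'   `phi` columns (vectorised).
#' @param rule a [posture_rule()].
#' @return `"good"` or `"poor"` (character, vectorised over rows).
#' @export
assess_posture <- function(angles, rule = posture_rule()) {
  if (!inherits(rule, "posture_rule")) stop_belt("rule must be a posture_rule")
  psi <- if (is.data.frame(angles)) angles$psi else angles[["psi"]]
  phi <- if (is.data.frame(angles)) angles$phi else angles[["phi"]]
  good <- abs(psi) <= rule$psi_tolerance &
    phi >= rule$phi_min & phi <= rule$phi_max
  ifelse(good, "good", "poor")
}

#' Per-sample posture assessment of a recording
#'
#' Computes attitude angles on the low-passed gravity component (0.3 Hz)
#' rather than raw acceleration, so transient body motion does not flip
#' the good/poor assessment, then applies the rule per sample.
#'
#' @param rec an [imu_recording()].
#' @param rule a [posture_rule()].
#' @return Data frame with `t`, `theta`, `psi`, `phi`, `posture`.
#' @export
monitor_posture <- function(rec, rule = posture_rule()) {
  gravity <- separate_gravity(denoise(rec$acc, rec$sample_rate),
                              rec$sample_rate)$gravity
  angles <- attitude_angles(gravity)
  data.frame(t = rec$time, angles, posture = assess_posture(angles, rule))
}

#' Poor-posture rate of a session
#'
#' Fraction of assessed time spent in poor posture — the per-session
#' statistic used to compare intervention-on and intervention-off blocks.
#'
#' @param assessments character vector of `"good"` / `"poor"`, one per
#'   uniformly spaced sample.
#' @param sample_rate assessment rate in Hz (default 1).
#' @return A `session_stats` list: `poor_posture_rate` in `[0, 1]`,
#'   `duration` in seconds, `n`.
#' @export
poor_posture_rate <- function(assessments, sample_rate = 1) {
  if (length(assessments) == 0) stop_belt("empty assessment series")
  if (!all(assessments %in% c("good", "poor"))) {
    stop_belt("assessments must be 'good' or 'poor'")
  }
  structure(
    list(poor_posture_rate = mean(assessments == "poor"),
         duration = length(assessments) / sample_rate,
         n = length(assessments)),
    class = "session_stats"
  )
}

#' Posture improvement rate between two sessions
#'
#' Percentage reduction of the poor-posture rate from a no-intervention
#' session to an intervention session:
#' `100 * (rate_without - rate_with) / rate_without`.
#'
#' @param rate_without poor-posture rate without intervention (must be
#'   positive).
#' @param rate_with poor-posture rate with intervention.
#' @return Improvement in percent (negative when posture worsened).
#' @export
improvement_rate <- function(rate_without, rate_with) {
  if (rate_without <= 0) {
    stop_belt("improvement rate undefined: baseline poor-posture rate is zero")
  }
  100 * (rate_without - rate_with) / rate_without
}
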