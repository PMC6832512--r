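# Stylised activity kinematics: each activity is a gravity orientation in
# the belt frame (X up when upright, Z anterior) plus sinusoidal motion
# components at a characteristic cadence, with white noise. The goal is a
# controllable, fully seeded test substrate with class structure in the
# same places real belt data has it (gravity direction for static
# postures, cadence/amplitude/harmonics for locomotion) — not a
# biomechanical gait simulation.
activity_templates <- function() {
  list(
    lay_down = list(
      gravity = c(0, 0, 1), noise = 0.008, gyro_noise = 0.01,
      acc_comp = list(), gyro_comp = list()
    ),
    sit = list(
      # reclined ~12 degrees toward the anterior axis
      gravity = c(cos(12 * pi / 180), 0, sin(12 * pi / 180)),
      noise = 0.008, gyro_noise = 0.01,
      acc_comp = list(list(freq = 0.25, amp = c(0.004, 0.006, 0.004))),
      gyro_comp = list()
    ),
    stand = list(
      gravity = c(1, 0, 0), noise = 0.01, gyro_noise = 0.012,
      acc_comp = list(list(freq = 0.4, amp = c(0.006, 0.01, 0.006))),
      gyro_comp = list(list(freq = 0.4, amp = c(0.01, 0.01, 0.01)))
    ),
    walk = list(
      gravity = c(1, 0, 0), noise = 0.03, gyro_noise = 0.05,
      acc_comp = list(
        list(freq = 1.8, amp = c(0.25, 0.05, 0.15)),
        list(freq = 0.9, amp = c(0.03, 0.10, 0.03)),
        list(freq = 3.6, amp = c(0.08, 0.02, 0.05))
      ),
      gyro_comp = list(list(freq = 1.8, amp = c(0.15, 0.30, 0.20)))
    ),
    walk_downstairs = list(
      gravity = c(cos(-5 * pi / 180), 0, sin(-5 * pi / 180)),
      noise = 0.04, gyro_noise = 0.07,
      acc_comp = list(
        list(freq = 1.5, amp = c(0.45, 0.10, 0.22)),
        list(freq = 3.0, amp = c(0.22, 0.05, 0.10)),  # landing impacts
        list(freq = 4.5, amp = c(0.10, 0.02, 0.05))
      ),
      gyro_comp = list(list(freq = 1.5, amp = c(0.25, 0.45, 0.30)))
    ),
    walk_upstairs = list(
      gravity = c(cos(8 * pi / 180), 0, sin(8 * pi / 180)),
      noise = 0.035, gyro_noise = 0.06,
      acc_comp = list(
        list(freq = 1.5, amp = c(0.30, 0.08, 0.25)),
        list(freq = 3.0, amp = c(0.08, 0.03, 0.06))
      ),
      gyro_comp = list(list(freq = 1.5, amp = c(0.20, 0.40, 0.25)))
    ),
    run = list(
      gravity = c(1, 0, 0), noise = 0.06, gyro_noise = 0.10,
      acc_comp = list(
        list(freq = 2.8, amp = c(0.70, 0.12, 0.30)),
        list(freq = 5.6, amp = c(0.25, 0.05, 0.10))
      ),
      gyro_comp = list(list(freq = 2.8, amp = c(0.40, 0.80, 0.50)))
    )
  )
}

#' Synthetic subject profile
#'
#' Per-subject multipliers emulating individual differences (physique,
#' gait): an overall motion amplitude gain, a cadence factor, a fixed
#' baseline tilt of the buckle (rotation of the gravity direction in the
#' X-Z and X-Y planes), and a noise scale. `heterogeneity` scales all
#' deviations from the population default; 0 gives identical subjects.
#'
#' @param id subject identifier.
#' @param seed RNG seed for drawing this subject's parameters.
#' @param heterogeneity non-negative scale of between-subject variation
#'   (default 1).
#' @return A `subject_profile` list with `id`, `gain`, `cadence_factor`,
#'   `tilt_z`, `tilt_y` (degrees), `noise_scale`, `seed`.
#' @export
subject_profile <- function(id, seed = 1, heterogeneity = 1) {
  if (heterogeneity < 0) stop_belt("heterogeneity must be non-negative")
  with_seed(seed, {
    structure(list(
      id = id,
      gain = max(1 + heterogeneity * runif(1, -0.25, 0.25), 0.1),
      cadence_factor = 1 + heterogeneity * runif(1, -0.1, 0.1),
      tilt_z = heterogeneity * rnorm(1, 0, 6),
      tilt_y = heterogeneity * rnorm(1, 0, 4),
      noise_scale = max(1 + heterogeneity * runif(1, -0.2, 0.5), 0.1),
      seed = seed
    ), class = "subject_profile")
  })
}

default_subject <- function() {
  structure(list(id = "default", gain = 1, cadence_factor = 1, tilt_z = 0,
                 tilt_y = 0, noise_scale = 1, seed = 0),
            class = "subject_profile")
}

# pitch = rotation in the X-Z plane (about Y)
rot_pitch <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Generate a synthetic labelled belt recording of one activity
#'
#' Renders the activity's template (gravity orientation + sinusoidal
#' motion components + Gaussian noise) through the subject's profile. The
#' output is deterministic given the seed; changing only the seed changes
#' only the noise and phase realisations, never the class structure.
#'
#' @param label one of [ACTIVITY_LABELS].
#' @param duration recording length in seconds.
#' @param subject a [subject_profile()] (default: the population default).
#' @param sample_rate sampling rate in Hz (default 100).
#' @param seed RNG seed (default 1).
#' @return A labelled [imu_recording()].
#' @export
generate_activity <- function(label, duration, subject = NULL,
                              sample_rate = 100, seed = 1) {
  tpl <- activity_templates()[[label]]
  if (is.null(tpl)) {
    stop_belt(sprintf("unknown activity label '%s'", label))
  }
  if (duration <= 0) stop_belt("duration must be positive")
  if (is.null(subject)) subject <- default_subject()
  n <- round(duration * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  tilt <- rot_pitch(subject$tilt_z) %*% rot_yaw(subject$tilt_y)
  gdir <- as.numeric(tilt %*% tpl$gravity)

  with_seed(seed, {
    acc <- matrix(rnorm(n * 3, 0, tpl$noise * subject$noise_scale), n, 3)
    gyro <- matrix(rnorm(n * 3, 0, tpl$gyro_noise * subject$noise_scale), n, 3)
    for (comp in tpl$acc_comp) {
      phase <- runif(3, 0, 2 * pi)
      f <- comp$freq * subject$cadence_factor
      for (a in 1:3) {
        dir_amp <- as.numeric(tilt %*% (comp$amp * (seq_len(3) == a)))
        wave <- subject$gain * sin(2 * pi * f * tt + phase[a])
        acc <- acc + outer(wave, dir_amp)
      }
    }
    for (comp in tpl$gyro_comp) {
      phase <- runif(3, 0, 2 * pi)
      f <- comp$freq * subject$cadence_factor
      for (a in 1:3) {
        gyro[, a] <- gyro[, a] +
          subject$gain * comp$amp[a] * sin(2 * pi * f * tt + phase[a])
      }
    }
    acc <- acc + matrix(gdir, n, 3, byrow = TRUE)
    imu_recording(acc, gyro, sample_rate = sample_rate,
                  labels = rep(label, n))
  })
}

# yaw = rotation in the X-Y plane (about Z)
rot_yaw <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Generate a balanced multi-subject labelled window dataset
#'
#' For each synthetic subject, generates one recording per activity, runs
#' the full signal-derivation + feature-extraction pipeline, and stacks
#' the labelled windows. The result is the test substrate for the
#' recognition model: balanced over the 7 classes, with between-subject
#' heterogeneity controlled by `heterogeneity`.
#'
#' @param n_subjects number of synthetic subjects (default 17).
#' @param duration seconds of recording per activity per subject
#'   (default 16, i.e. 24 windows per class per subject at 100 Hz).
#' @param sample_rate sampling rate in Hz (default 100).
#' @param heterogeneity between-subject variation scale (default 1; 0
#'   makes subjects exchangeable).
#' @param seed master RNG seed; per-subject and per-recording seeds are
#'   derived from it.
#' @return A `belt_dataset`: list with `features` (n x 561 matrix),
#'   `labels` (character), `subject` (character), `start` (window
#'   offsets), `n_subjects`, `heterogeneity`, `seed`.
#' @export
generate_dataset <- function(n_subjects = 17, duration = 16,
                             sample_rate = 100, heterogeneity = 1,
                             seed = 1) {
  if (n_subjects < 1) stop_belt("n_subjects must be at least 1")
  parts <- vector("list", n_subjects * length(ACTIVITY_LABELS))
  k <- 0L
  for (s in seq_len(n_subjects)) {
    subj <- subject_profile(
      id = sprintf("S%02d", s),
      seed = (seed * 1000 + s) %% 2147483647,
      heterogeneity = heterogeneity
    )
    for (li in seq_along(ACTIVITY_LABELS)) {
      label <- ACTIVITY_LABELS[li]
      rec <- generate_activity(
        label, duration, subject = subj, sample_rate = sample_rate,
        seed = (seed * 100000 + s * 100 + li) %% 2147483647
      )
      rf <- recording_features(rec)
      k <- k + 1L
      parts[[k]] <- list(features = rf$features, labels = rf$labels,
                         subject = rep(subj$id, nrow(rf$features)),
                         start = rf$starts)
    }
  }
  structure(
    list(
      features = do.call(rbind, lapply(parts, `[[`, "features")),
      labels = unlist(lapply(parts, `[[`, "labels")),
      subject = unlist(lapply(parts, `[[`, "subject")),
      start = unlist(lapply(parts, `[[`, "start")),
      n_subjects = n_subjects, heterogeneity = heterogeneity, seed = seed
    ),
    class = "belt_dataset"
  )
}

#' @export
print.belt_dataset <- function(x, ...) {
  cat(sprintf("<belt_dataset> %d windows x %d features, %d subjects, heterogeneity %g\n",
              nrow(x$features), ncol(x$features), x$n_subjects,
              x$heterogeneity))
  print(table(x$labels))
  invisible(x)
}

#' Generate a synthetic magnetometer insertion trace
#'
#' Emulates the buckle blade riding the sawtooth belt surface during one
#' monotone insertion at constant speed: blade displacement is a sawtooth
#' wave of the insertion position (one ramp per 0.6 cm tooth, sharp drop
#' at the tooth edge), rendered as a magnetometer amplitude plus optional
#' baseline, linear drift and Gaussian noise. A fractional final tooth is
#' rendered as a partial ramp.
#'
#' @param insertion_cm true insertion distance in cm (non-negative).
#' @param pitch_cm tooth pitch in cm (default 0.6).
#' @param sample_rate sampling rate in Hz (default 100).
#' @param speed_cm_s insertion speed in cm/s (default 2, i.e. 30 samples
#'   per tooth at the defaults).
#' @param amplitude peak-to-peak cycle amplitude (default 1, arbitrary
#'   field units).
#' @param baseline constant offset (default 0).
#' @param drift linear baseline drift over the whole trace (default 0).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed RNG seed for the noise (default 1).
#' @return A [mag_trace()].
#' @export
generate_mag_trace <- function(insertion_cm, pitch_cm = 0.6,
                               sample_rate = 100, speed_cm_s = 2,
                               amplitude = 1, baseline = 0, drift = 0,
                               noise_sd = 0, seed = 1) {
  if (insertion_cm < 0) stop_belt("insertion_cm must be non-negative")
  if (pitch_cm <= 0 || speed_cm_s <= 0) {
    stop_belt("pitch_cm and speed_cm_s must be positive")
  }
  # lead-in/out at rest so the trace starts and ends off the ramp
  rest <- round(0.25 * sample_rate)
  n_move <- max(round(insertion_cm / speed_cm_s * sample_rate), 1)
  pos <- c(rep(0, rest),
           seq(0, insertion_cm, length.out = n_move),
           rep(insertion_cm, rest))
  phase <- pos / pitch_cm
  values <- amplitude * (phase - floor(phase))
  n <- length(values)
  values <- values + baseline + drift * seq(0, 1, length.out = n)
  if (noise_sd > 0) {
    values <- with_seed(seed, values + rnorm(n, 0, noise_sd))
  }
  mag_trace(values, sample_rate)
}
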