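#' Construct a belt IMU recording
#'
#' Container for a uniformly sampled tri-axial accelerometer + gyroscope
#' stream from the belt buckle. Acceleration is kept in gravitational units
#' (g) and angular velocity in rad/s throughout the package; unit conversion
#' belongs at the I/O boundary.
#'
#' Axis convention (fixed, documented rather than inferred from hardware):
#' with the wearer upright, X points up along the trunk, Y is lateral
#' (wearer's left) and Z is anterior (away from the body). Gravity therefore
#' loads the X axis when standing and the Z axis when lying supine.
#'
#' @param acc numeric matrix, n x 3, acceleration in g (columns X, Y, Z).
#' @param gyro numeric matrix, n x 3, angular velocity in rad/s.
#' @param sample_rate sampling rate in Hz (default 100, so a 128-sample
#'   analysis window spans 1.28 s).
#' @param labels optional per-sample activity tag (character or factor,
#'   length n).
#' @param time optional time stamps in seconds; must be a uniform strictly
#'   increasing grid at `1/sample_rate` spacing. Generated when omitted.
#' @return An object of class `imu_recording`: list with elements `acc`,
#'   `gyro`, `sample_rate`, `time`, `labels`.
#' @examples
#' rec <- imu_recording(matrix(c(0, 0, 1), 256, 3, byrow = TRUE),
#'                      matrix(0, 256, 3))
#' rec
#' @export
imu_recording <- function(acc, gyro, sample_rate = 100, labels = NULL,
                          time = NULL) {
  acc <- as_xyz(acc, "acc")
  gyro <- as_xyz(gyro, "gyro")
  n <- nrow(acc)
  if (nrow(gyro) != n) {
    stop_belt("acc and gyro must have the same number of samples")
  }
  if (n < 1) stop_belt("recording must contain at least one sample")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop_belt("sample_rate must be a single positive number (Hz)")
  }
  assert_finite(acc, "acc")
  assert_finite(gyro, "gyro")
  if (is.null(time)) {
    time <- seq_len(n - 1L)
    time <- c(0, time) / sample_rate
  } else {
    time <- as.numeric(time)
    if (length(time) != n) stop_belt("time must match the sample count")
    check_uniform_time(time, sample_rate)
  }
  if (!is.null(labels)) {
    if (length(labels) != n) {
      stop_belt("labels must be one tag per sample")
    }
    labels <- as.character(labels)
  }
  structure(
    list(acc = acc, gyro = gyro, sample_rate = sample_rate,
         time = time, labels = labels),
    class = "imu_recording"
  )
}

as_xyz <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) {
    stop_belt(sprintf("%s must have exactly 3 columns (X, Y, Z)", what))
  }
  storage.mode(x) <- "double"
  colnames(x) <- c("X", "Y", "Z")
  x
}

# Uniform-grid invariant: spacing equal to 1/sample_rate within 1e-9
# relative tolerance.
check_uniform_time <- function(time, sample_rate) {
  if (length(time) < 2) return(invisible(time))
  dt <- diff(time)
  target <- 1 / sample_rate
  if (any(dt <= 0) || max(abs(dt - target)) > 1e-9 * max(target, 1)) {
    stop_belt("time stamps must form a strictly increasing uniform grid at 1/sample_rate spacing")
  }
  invisible(time)
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- nrow(x$acc)
  cat(sprintf("<imu_recording> %d samples @ %g Hz (%.2f s)\n",
              n, x$sample_rate, n / x$sample_rate))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an [imu_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$acc)

#' Read / write belt IMU recordings as CSV
#'
#' The on-disk format is one row per sample with header
#' `t,acc_x,acc_y,acc_z,gyro_x,gyro_y,gyro_z[,label]`. Values round-trip
#' losslessly (written at full double precision); the sample rate is
#' recovered from the time column.
#'
#' @param path file path.
#' @param sample_rate optional rate override in Hz; by default inferred from
#'   the median spacing of the `t` column and then validated against the
#'   uniform-grid invariant.
#' @return `read_imu_csv()` returns an [imu_recording()];
#'   `write_imu_csv()` returns `path` invisibly.
#' @export
read_imu_csv <- function(path, sample_rate = NULL) {
  if (!file.exists(path)) {
    stop_belt(sprintf("recording file not found: %s", path))
  }
  df <- read.csv(path, check.names = FALSE)
  need <- c("t", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_belt(sprintf("malformed recording CSV %s: missing column(s) %s",
                      path, paste(missing_cols, collapse = ", ")))
  }
  for (col in need) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop_belt(sprintf("malformed recording CSV %s: bad value in column '%s' at data line %d",
                        path, col, bad[1]))
    }
    df[[col]] <- vals
  }
  if (is.null(sample_rate)) {
    if (nrow(df) < 2) stop_belt("cannot infer sample_rate from a single row")
    sample_rate <- 1 / median(diff(df$t))
  }
  imu_recording(
    acc = cbind(df$acc_x, df$acc_y, df$acc_z),
    gyro = cbind(df$gyro_x, df$gyro_y, df$gyro_z),
    sample_rate = sample_rate,
    labels = if ("label" %in% names(df)) df$label else NULL,
    time = df$t
  )
}

#' @rdname read_imu_csv
#' @param rec an [imu_recording()].
#' @export
write_imu_csv <- function(rec, path) {
  df <- data.frame(
    t = rec$time,
    acc_x = rec$acc[, 1], acc_y = rec$acc[, 2], acc_z = rec$acc[, 3],
    gyro_x = rec$gyro[, 1], gyro_y = rec$gyro[, 2], gyro_z = rec$gyro[, 3]
  )
  if (!is.null(rec$labels)) df$label <- rec$labels
  # full precision so the round trip is exact
  old <- options(digits = 17)
  on.exit(options(old))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
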