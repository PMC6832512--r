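# Frozen enumeration of the 561-element feature vector.
#
# Per tri-axial time channel (5): mean, std, mad, max, min per axis (15),
#   sma (1), energy/iqr/entropy per axis (9), four Burg AR coefficients per
#   axis (12), pairwise correlations X-Y, X-Z, Y-Z (3)          -> 40 x 5
# Per magnitude time channel (5): mean, std, mad, max, min, sma, energy,
#   iqr, entropy, four AR coefficients                          -> 13 x 5
# Per tri-axial frequency channel (3): mean, std, mad, max, min per axis,
#   sma, energy/iqr/entropy per axis, maxInds/meanFreq/skewness/kurtosis
#   per axis (37), band energies over 14 fixed bands of the 64 non-DC bins
#   per axis (42)                                               -> 79 x 3
# Per magnitude frequency channel (4): the 13 scalar spectrum statistics
#                                                               -> 13 x 4
# Angles between window-mean vectors and the gravity direction  ->  7
# Total: 200 + 65 + 237 + 52 + 7 = 561.

TIME_XYZ <- c("tBodyAcc", "tGravityAcc", "tBodyAccJerk", "tBodyGyro",
              "tBodyGyroJerk")
TIME_MAG <- c("tBodyAccMag", "tGravityAccMag", "tBodyAccJerkMag",
              "tBodyGyroMag", "tBodyGyroJerkMag")
FREQ_XYZ <- c("fBodyAcc", "fBodyAccJerk", "fBodyGyro")
FREQ_MAG <- c("fBodyAccMag", "fBodyAccJerkMag", "fBodyGyroMag",
              "fBodyGyroJerkMag")

# 14 fixed bands over the 64 non-DC bins of the 128-sample window spectrum:
# eight 8-bin bands, four 16-bin bands, two 24-bin bands.
BAND_LIMITS <- rbind(
  cbind(seq(1, 57, by = 8), seq(8, 64, by = 8)),
  cbind(seq(1, 49, by = 16), seq(16, 64, by = 16)),
  cbind(c(1, 25), c(24, 48))
)

AXES <- c("X", "Y", "Z")

# Compute the full ordered feature vector for one window. idx indexes the
# time channels, w the per-window spectra.
compute_window_features <- function(signals, idx, w) {
  out <- numeric(561)
  nms <- character(561)
  k <- 0L
  add <- function(name, value) {
    n <- length(value)
    out[k + seq_len(n)] <<- value
    nms[k + seq_len(n)] <<- name
    k <<- k + n
  }

  scalar_stats_xyz <- function(sig, x) {
    add(paste0(sig, "-mean()-", AXES), apply(x, 2, ft_mean))
    add(paste0(sig, "-std()-", AXES), apply(x, 2, ft_std))
    add(paste0(sig, "-mad()-", AXES), apply(x, 2, ft_mad))
    add(paste0(sig, "-max()-", AXES), apply(x, 2, ft_max))
    add(paste0(sig, "-min()-", AXES), apply(x, 2, ft_min))
    add(paste0(sig, "-sma()"), ft_sma(x[, 1], x[, 2], x[, 3]))
    add(paste0(sig, "-energy()-", AXES), apply(x, 2, ft_energy))
    add(paste0(sig, "-iqr()-", AXES), apply(x, 2, ft_iqr))
    add(paste0(sig, "-entropy()-", AXES), apply(x, 2, ft_entropy))
  }

  for (sig in TIME_XYZ) {
    x <- signals[[sig]][idx, , drop = FALSE]
    scalar_stats_xyz(sig, x)
    for (a in 1:3) {
      add(paste0(sig, "-arCoeff()-", AXES[a], ",", 1:4), ft_ar_burg(x[, a]))
    }
    add(paste0(sig, "-correlation()-X,Y"), ft_correlation(x[, 1], x[, 2]))
    add(paste0(sig, "-correlation()-X,Z"), ft_correlation(x[, 1], x[, 3]))
    add(paste0(sig, "-correlation()-Y,Z"), ft_correlation(x[, 2], x[, 3]))
  }

  for (sig in TIME_MAG) {
    s <- signals[[sig]][idx]
    add(paste0(sig, "-mean()"), ft_mean(s))
    add(paste0(sig, "-std()"), ft_std(s))
    add(paste0(sig, "-mad()"), ft_mad(s))
    add(paste0(sig, "-max()"), ft_max(s))
    add(paste0(sig, "-min()"), ft_min(s))
    add(paste0(sig, "-sma()"), ft_sma(s))
    add(paste0(sig, "-energy()"), ft_energy(s))
    add(paste0(sig, "-iqr()"), ft_iqr(s))
    add(paste0(sig, "-entropy()"), ft_entropy(s))
    add(paste0(sig, "-arCoeff()", 1:4), ft_ar_burg(s))
  }

  for (sig in FREQ_XYZ) {
    x <- signals[[sig]][w, , ]  # n_bins x 3
    scalar_stats_xyz(sig, x)
    add(paste0(sig, "-maxInds-", AXES), apply(x, 2, ft_max_freq_ind))
    add(paste0(sig, "-meanFreq()-", AXES), apply(x, 2, ft_mean_freq))
    add(paste0(sig, "-skewness()-", AXES), apply(x, 2, ft_skewness))
    add(paste0(sig, "-kurtosis()-", AXES), apply(x, 2, ft_kurtosis))
    for (a in 1:3) {
      nodc <- x[-1, a]
      add(paste0(sig, "-bandsEnergy()-", BAND_LIMITS[, 1], ",",
                 BAND_LIMITS[, 2], "-", AXES[a]),
          vapply(seq_len(nrow(BAND_LIMITS)),
                 function(b) ft_energy_band(nodc, BAND_LIMITS[b, 1],
                                            BAND_LIMITS[b, 2]),
                 numeric(1)))
    }
  }

  for (sig in FREQ_MAG) {
    s <- signals[[sig]][w, ]
    add(paste0(sig, "-mean()"), ft_mean(s))
    add(paste0(sig, "-std()"), ft_std(s))
    add(paste0(sig, "-mad()"), ft_mad(s))
    add(paste0(sig, "-max()"), ft_max(s))
    add(paste0(sig, "-min()"), ft_min(s))
    add(paste0(sig, "-sma()"), ft_sma(s))
    add(paste0(sig, "-energy()"), ft_energy(s))
    add(paste0(sig, "-iqr()"), ft_iqr(s))
    add(paste0(sig, "-entropy()"), ft_entropy(s))
    add(paste0(sig, "-maxInds"), ft_max_freq_ind(s))
    add(paste0(sig, "-meanFreq()"), ft_mean_freq(s))
    add(paste0(sig, "-skewness()"), ft_skewness(s))
    add(paste0(sig, "-kurtosis()"), ft_kurtosis(s))
  }

  gmean <- colMeans(signals$tGravityAcc[idx, , drop = FALSE])
  mean_of <- function(sig) colMeans(signals[[sig]][idx, , drop = FALSE])
  add("angle(tBodyAccMean,gravityMean)", vec_angle(mean_of("tBodyAcc"), gmean))
  add("angle(tBodyAccJerkMean,gravityMean)",
      vec_angle(mean_of("tBodyAccJerk"), gmean))
  add("angle(tBodyGyroMean,gravityMean)", vec_angle(mean_of("tBodyGyro"), gmean))
  add("angle(tBodyGyroJerkMean,gravityMean)",
      vec_angle(mean_of("tBodyGyroJerk"), gmean))
  add("angle(X,gravityMean)", vec_angle(c(1, 0, 0), gmean))
  add("angle(Y,gravityMean)", vec_angle(c(0, 1, 0), gmean))
  add("angle(Z,gravityMean)", vec_angle(c(0, 0, 1), gmean))

  stopifnot(k == 561L)
  names(out) <- nms
  out
}

vec_angle <- function(u, v) {
  if (all(u == 0) || all(v == 0)) return(0)
  cross <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cross^2)), sum(u * v))
}

.beltsense_env <- new.env(parent = emptyenv())

#' The frozen 561 feature names
#'
#' Ordered names of the feature vector, in the `signal-function()-component`
#' notation standard in the HAR literature (e.g. `tBodyAcc-mean()-X`,
#' `fBodyAccMag-meanFreq()`, `angle(X,gravityMean)`). The order is stable
#' across runs and defines the column order of every feature matrix the
#' package produces.
#'
#' @return Character vector of length 561.
#' @export
feature_names <- function() {
  if (is.null(.beltsense_env$feature_names)) {
    rec <- imu_recording(
      acc = cbind(sin(1:160 / 9), cos(1:160 / 7), 1 + sin(1:160 / 5)),
      gyro = cbind(sin(1:160 / 4), cos(1:160 / 6), sin(1:160 / 8)),
      sample_rate = 100
    )
    sig <- derive_signals(rec)
    v <- compute_window_features(sig, 1:128, 1L)
    .beltsense_env$feature_names <- names(v)
  }
  .beltsense_env$feature_names
}

#' Extract the 561-element feature vector of one window
#'
#' @param signals a `belt_signals` object from [derive_signals()].
#' @param start 0-based window start offset; must be one of
#'   `signals$window_starts`.
#' @return A `feature_window` object: list with `start`, `features` (named
#'   numeric, length 561), and `label` (majority per-sample label of the
#'   window, ties broken by the earliest label; `NA` when the recording is
#'   unlabelled).
#' @export
extract_features <- function(signals, start) {
  if (!inherits(signals, "belt_signals")) {
    stop_belt("extract_features expects a belt_signals object")
  }
  w <- match(start, signals$window_starts)
  if (is.na(w)) {
    stop_belt(sprintf("start %s is not a window start of this signal set", start))
  }
  idx <- (start + 1):(start + signals$window)
  feats <- compute_window_features(signals, idx, w)
  bad <- which(!is.finite(feats))
  if (length(bad)) {
    stop_belt(sprintf("non-finite feature '%s' in window starting at %d",
                      names(feats)[bad[1]], start))
  }
  structure(
    list(start = start, features = feats,
         label = window_label(signals$labels, idx)),
    class = "feature_window"
  )
}

window_label <- function(labels, idx) {
  if (is.null(labels)) return(NA_character_)
  tags <- labels[idx]
  counts <- table(factor(tags, levels = unique(tags)))  # earliest-first ties
  names(counts)[which.max(counts)]
}

#' Extract features for every window of a recording
#'
#' Convenience wrapper: derives the 17 signals and computes the feature
#' vector of every 50 %-overlap window.
#'
#' @param rec an [imu_recording()].
#' @param window,overlap windowing parameters, see [make_windows()].
#' @param drop_mixed drop windows whose samples carry more than two
#'   distinct labels (activity transitions) instead of keeping the majority
#'   label (default `FALSE`).
#' @return A list with `features` (n_windows x 561 matrix), `labels`
#'   (character, `NA` when unlabelled), and `starts` (0-based offsets).
#' @export
recording_features <- function(rec, window = 128L, overlap = 0.5,
                               drop_mixed = FALSE) {
  signals <- derive_signals(rec, window = window, overlap = overlap)
  starts <- signals$window_starts
  keep <- rep(TRUE, length(starts))
  if (drop_mixed && !is.null(signals$labels)) {
    for (i in seq_along(starts)) {
      idx <- (starts[i] + 1):(starts[i] + signals$window)
      keep[i] <- length(unique(signals$labels[idx])) <= 2
    }
  }
  starts <- starts[keep]
  feats <- matrix(0, length(starts), 561,
                  dimnames = list(NULL, feature_names()))
  labs <- character(length(starts))
  for (i in seq_along(starts)) {
    fw <- extract_features(signals, starts[i])
    feats[i, ] <- fw$features
    labs[i] <- fw$label
  }
  list(features = feats, labels = labs, starts = starts)
}

#' Fit / apply per-feature standardization
#'
#' `fit_standardizer()` estimates a per-feature location (mean) and scale
#' (sample standard deviation) on training windows only; frozen parameters
#' are then applied to held-out data so no test information leaks into the
#' transform. Degenerate features (scale below `1e-12`) get scale 1 and are
#' flagged, so constant columns standardize to 0 instead of NaN.
#'
#' @param x numeric feature matrix (rows = windows), 561 columns.
#' @return `fit_standardizer()`: a `belt_standardizer` with `center`,
#'   `scale`, `degenerate`; `apply_standardizer()`: the transformed matrix.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_belt("fit_standardizer needs at least 2 windows")
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  degenerate <- !is.finite(scale) | scale < 1e-12
  scale[degenerate] <- 1
  structure(list(center = center, scale = scale, degenerate = degenerate),
            class = "belt_standardizer")
}

#' @rdname fit_standardizer
#' @param params a `belt_standardizer`.
#' @export
apply_standardizer <- function(params, x) {
  if (!inherits(params, "belt_standardizer")) {
    stop_belt("params must come from fit_standardizer()")
  }
  if (inherits(x, "feature_window")) {
    x$features <- (x$features - params$center) / params$scale
    return(x)
  }
  x <- as.matrix(x)
  if (ncol(x) != length(params$center)) {
    stop_belt(sprintf("feature matrix has %d columns, expected %d",
                      ncol(x), length(params$center)))
  }
  assert_finite(x, "features to standardize")
  sweep(sweep(x, 2, params$center), 2, params$scale, "/")
}
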