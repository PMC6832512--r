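#' Windowed feature functions
#'
#' Scalar (or small-vector) statistics computed on one 128-sample window of
#' a derived signal; the building blocks of the 561-element feature vector.
#' Conventions frozen here so feature values are bit-reproducible:
#'
#' * `ft_std()` and the moment-based `ft_skewness()` / `ft_kurtosis()` use
#'   population (1/N) moments; kurtosis is the raw (non-excess) ratio
#'   `E[(s-m)^4] / E[(s-m)^2]^2`. A zero-variance window yields 0 for both
#'   shape statistics so vectors stay finite.
#' * `ft_energy()` is the mean of squares, `ft_rms()` its square root.
#' * `ft_sma()` (signal magnitude area) averages the mean absolute value
#'   over the channels supplied, i.e. `1/(kN) * sum |s|` for k channels —
#'   window-length invariant.
#' * `ft_entropy()` is Shannon entropy (natural log) of the window's
#'   absolute values normalised to weights, with `0 * log 0 = 0`; an
#'   all-zero window has entropy 0.
#' * `ft_iqr()` uses the linear-interpolation quantile definition
#'   (`stats::quantile` type 7).
#' * `ft_correlation()` of a (near-)constant channel is defined as 0.
#' * `ft_ar_burg()` returns the four coefficients of an order-4 Burg
#'   autoregressive fit without mean removal; zero-variance windows give
#'   four zeros.
#' * `ft_angle()` returns `atan2(|m x v|, m . v)` in radians, the angle in
#'   `[0, pi]` between the per-channel window means `m = (mean(s1),
#'   mean(s2), mean(s3))` and a reference vector `v`; 0 if either vector is
#'   zero.
#' * `ft_max_freq_ind()` is the 1-based index of the largest spectral
#'   component; `ft_mean_freq()` the index-weighted average
#'   `sum(i * s_i) / sum(s_j)` (0 for an all-zero spectrum);
#'   `ft_energy_band(s, a, b)` the mean of squares over indices `a:b`.
#'
#' @param s,s1,s2,s3 numeric windows (for frequency features, the one-sided
#'   magnitude spectrum from [to_frequency()]).
#' @param v numeric length-3 reference vector for `ft_angle()`.
#' @param a,b integer band limits (inclusive, `a <= b`) for
#'   `ft_energy_band()`.
#' @return A scalar, except `ft_ar_burg()` which returns 4 coefficients.
#' @name feature_functions
NULL

#' @rdname feature_functions
#' @export
ft_mean <- function(s) sum(s) / length(s)

#' @rdname feature_functions
#' @export
ft_std <- function(s) sqrt(ft_energy(s - ft_mean(s)))

#' @rdname feature_functions
#' @export
ft_mad <- function(s) median(abs(s - median(s)))

#' @rdname feature_functions
#' @export
ft_max <- function(s) max(s)

#' @rdname feature_functions
#' @export
ft_min <- function(s) min(s)

#' @rdname feature_functions
#' @export
ft_energy <- function(s) sum(s^2) / length(s)

#' @rdname feature_functions
#' @export
ft_sma <- function(s1, s2 = NULL, s3 = NULL) {
  chans <- Filter(Negate(is.null), list(s1, s2, s3))
  mean(vapply(chans, function(s) mean(abs(s)), numeric(1)))
}

#' @rdname feature_functions
#' @export
ft_entropy <- function(s) {
  tot <- sum(abs(s))
  if (tot == 0) return(0)
  w <- abs(s) / tot
  w <- w[w > 0]
  -sum(w * log(w))
}

#' @rdname feature_functions
#' @export
ft_iqr <- function(s) {
  q <- quantile(s, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' @rdname feature_functions
#' @export
ft_ar_burg <- function(s) {
  v <- ft_energy(s - ft_mean(s))
  if (!is.finite(v)) return(rep(NA_real_, 4))
  if (v < 1e-24) return(numeric(4))
  fit <- tryCatch(
    ar.burg(s, aic = FALSE, order.max = 4, demean = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit) || length(fit$ar) != 4 || !all(is.finite(fit$ar))) {
    return(numeric(4))
  }
  as.numeric(fit$ar)
}

#' @rdname feature_functions
#' @export
ft_correlation <- function(s1, s2) {
  m1 <- ft_mean(s1); m2 <- ft_mean(s2)
  v1 <- sum((s1 - m1)^2); v2 <- sum((s2 - m2)^2)
  if (!is.finite(v1) || !is.finite(v2)) return(NA_real_)
  if (v1 <= 0 || v2 <= 0) return(0)
  sum((s1 - m1) * (s2 - m2)) / sqrt(v1 * v2)
}

#' @rdname feature_functions
#' @export
ft_angle <- function(s1, s2, s3, v) {
  m <- c(ft_mean(s1), ft_mean(s2), ft_mean(s3))
  if (all(m == 0) || all(v == 0)) return(0)
  cross <- c(m[2] * v[3] - m[3] * v[2],
             m[3] * v[1] - m[1] * v[3],
             m[1] * v[2] - m[2] * v[1])
  atan2(sqrt(sum(cross^2)), sum(m * v))
}

#' @rdname feature_functions
#' @export
ft_range <- function(s) max(s) - min(s)

#' @rdname feature_functions
#' @export
ft_rms <- function(s) sqrt(ft_energy(s))

#' @rdname feature_functions
#' @export
ft_skewness <- function(s) {
  m <- ft_mean(s)
  v <- ft_energy(s - m)
  if (v < 1e-24) return(0)
  mean(((s - m) / sqrt(v))^3)
}

#' @rdname feature_functions
#' @export
ft_kurtosis <- function(s) {
  m <- ft_mean(s)
  v <- ft_energy(s - m)
  if (v < 1e-24) return(0)
  mean((s - m)^4) / v^2
}

#' @rdname feature_functions
#' @export
ft_max_freq_ind <- function(s) which.max(s)

#' @rdname feature_functions
#' @export
ft_mean_freq <- function(s) {
  tot <- sum(s)
  if (tot == 0) return(0)
  sum(seq_along(s) * s) / tot
}

#' @rdname feature_functions
#' @export
ft_energy_band <- function(s, a, b) {
  if (a < 1 || b > length(s) || a > b) {
    stop_belt("ft_energy_band: band [a, b] must lie inside the spectrum")
  }
  sum(s[a:b]^2) / (b - a + 1)
}
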