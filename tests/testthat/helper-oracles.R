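# Independent brute-force implementations of every windowed feature
# formula, written directly from the printed definitions with plain loops.
# These never call the package's ft_* functions; they are the reference the
# implementation is checked against.

o_mean <- function(s) {
  tot <- 0
  for (v in s) tot <- tot + v
  tot / length(s)
}

o_std <- function(s) {
  m <- o_mean(s)
  tot <- 0
  for (v in s) tot <- tot + (v - m)^2
  sqrt(tot / length(s))
}

o_median <- function(s) {
  s <- sort(s)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

o_mad <- function(s) {
  m <- o_median(s)
  o_median(abs(s - m))
}

o_max <- function(s) {
  best <- s[1]
  for (v in s) if (v > best) best <- v
  best
}

o_min <- function(s) {
  best <- s[1]
  for (v in s) if (v < best) best <- v
  best
}

o_energy <- function(s) {
  tot <- 0
  for (v in s) tot <- tot + v * v
  tot / length(s)
}

# signal magnitude area, averaged over channels and window length
o_sma <- function(...) {
  chans <- list(...)
  tot <- 0
  for (ch in chans) {
    for (v in ch) tot <- tot + abs(v)
  }
  tot / (length(chans) * length(chans[[1]]))
}

o_entropy <- function(s) {
  tot <- 0
  for (v in s) tot <- tot + abs(v)
  if (tot == 0) return(0)
  h <- 0
  for (v in s) {
    w <- abs(v) / tot
    if (w > 0) h <- h - w * log(w)
  }
  h
}

# linear-interpolation quantile (type 7), by hand
o_quantile7 <- function(s, p) {
  s <- sort(s)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

o_iqr <- function(s) o_quantile7(s, 0.75) - o_quantile7(s, 0.25)

# Burg recursion, order p, no mean removal; returns phi with
# x_t = sum phi_i x_{t-i} + e_t
o_burg <- function(x, p) {
  n <- length(x)
  ef <- x
  eb <- x
  a <- numeric(0)
  for (m in seq_len(p)) {
    fm <- ef[(m + 1):n]
    bm <- eb[m:(n - 1)]
    denom <- sum(fm^2) + sum(bm^2)
    if (denom == 0) return(numeric(p))
    k <- -2 * sum(fm * bm) / denom
    a <- c(a + k * rev(a), k)
    efn <- ef
    ebn <- eb
    efn[(m + 1):n] <- fm + k * bm
    ebn[(m + 1):n] <- bm + k * fm
    ef <- efn
    eb <- ebn
  }
  -a
}

o_correlation <- function(s1, s2) {
  m1 <- o_mean(s1)
  m2 <- o_mean(s2)
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_along(s1)) {
    sxy <- sxy + (s1[i] - m1) * (s2[i] - m2)
    sxx <- sxx + (s1[i] - m1)^2
    syy <- syy + (s2[i] - m2)^2
  }
  if (sxx <= 0 || syy <= 0) return(0)
  sxy / sqrt(sxx * syy)
}

o_angle <- function(s1, s2, s3, v) {
  m <- c(o_mean(s1), o_mean(s2), o_mean(s3))
  if (all(m == 0) || all(v == 0)) return(0)
  cx <- m[2] * v[3] - m[3] * v[2]
  cy <- m[3] * v[1] - m[1] * v[3]
  cz <- m[1] * v[2] - m[2] * v[1]
  atan2(sqrt(cx^2 + cy^2 + cz^2), m[1] * v[1] + m[2] * v[2] + m[3] * v[3])
}

o_range <- function(s) o_max(s) - o_min(s)

o_rms <- function(s) sqrt(o_energy(s))

o_skewness <- function(s) {
  m <- o_mean(s)
  v <- o_energy(s - m)
  if (v < 1e-24) return(0)
  tot <- 0
  for (x in s) tot <- tot + ((x - m) / sqrt(v))^3
  tot / length(s)
}

o_kurtosis <- function(s) {
  m <- o_mean(s)
  v <- o_energy(s - m)
  if (v < 1e-24) return(0)
  tot <- 0
  for (x in s) tot <- tot + (x - m)^4
  (tot / length(s)) / v^2
}

o_max_freq_ind <- function(s) {
  best <- 1L
  for (i in seq_along(s)) if (s[i] > s[best]) best <- i
  best
}

o_mean_freq <- function(s) {
  num <- 0; den <- 0
  for (i in seq_along(s)) {
    num <- num + i * s[i]
    den <- den + s[i]
  }
  if (den == 0) return(0)
  num / den
}

o_energy_band <- function(s, a, b) {
  tot <- 0
  for (i in a:b) tot <- tot + s[i]^2
  tot / (b - a + 1)
}

# relative comparison used by the oracle-equivalence suites
expect_rel_equal <- function(actual, expected, rel_tol = 1e-9) {
  scale <- max(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected)) / scale, rel_tol)
}
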