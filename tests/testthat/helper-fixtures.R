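# Shared fixtures built in code at test time.

# static recording: buckle at rest with gravity on the given axis
static_recording <- function(n = 500, gdir = c(0, 0, 1), sample_rate = 100) {
  imu_recording(matrix(rep(gdir, each = n), n, 3),
                matrix(0, n, 3),
                sample_rate = sample_rate,
                labels = rep("lay_down", n))
}

# well-separated 561-feature classes: class k has mean offset on its own
# block of features, noise sd well below the offset
separable_features <- function(n_per_class = 30, classes = c("sit", "walk", "run"),
                               offset = 8, seed = 99) {
  k <- length(classes)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    x <- matrix(rnorm(n_per_class * k * 561), n_per_class * k, 561)
    labels <- rep(classes, each = n_per_class)
    for (i in seq_len(k)) {
      rows <- labels == classes[i]
      cols <- ((i - 1) * 10 + 1):(i * 10)
      x[rows, cols] <- x[rows, cols] + offset
    }
    colnames(x) <- feature_names()
    list(features = x, labels = labels)
  })
}

# small multi-subject pipeline dataset, cached across test files (the
# generation cost dominates otherwise)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(n_subjects = 3, duration = 8, seed = 11)
    }
    cache
  }
})
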