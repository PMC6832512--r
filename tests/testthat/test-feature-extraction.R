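test_that("every window yields exactly 561 named, finite features", {
  rec <- generate_activity("walk", 4, seed = 13)
  sig <- derive_signals(rec)
  for (start in sig$window_starts) {
    fw <- extract_features(sig, start)
    expect_length(fw$features, 561)
    expect_identical(names(fw$features), feature_names())
    expect_true(all(is.finite(fw$features)))
    expect_identical(fw$label, "walk")
  }
  expect_length(feature_names(), 561)
  expect_error(extract_features(sig, 1), "not a window start")
})

test_that("the feature enumeration is stable and deterministic", {
  # frozen anchors of the published order
  fn <- feature_names()
  expect_identical(fn[1], "tBodyAcc-mean()-X")
  expect_identical(fn[561], "angle(Z,gravityMean)")
  expect_identical(sum(grepl("bandsEnergy", fn)), 126L)
  expect_identical(sum(grepl("arCoeff", fn)), 80L)
  expect_identical(anyDuplicated(fn), 0L)

  # identical windows give identical vectors
  rec <- generate_activity("sit", 4, seed = 3)
  sig <- derive_signals(rec)
  f1 <- extract_features(sig, 64)
  f2 <- extract_features(sig, 64)
  expect_identical(f1$features, f2$features)

  # name order survives a serialization round trip
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(name = fn), path, row.names = FALSE)
  expect_identical(read.csv(path)$name, fn)
})

test_that("an all-zero recording produces the defined degenerate features", {
  zero <- imu_recording(matrix(0, 256, 3), matrix(0, 256, 3))
  sig <- derive_signals(zero)
  fw <- extract_features(sig, 0)
  f <- fw$features
  loc <- grep("-(mean|energy|std|mad|iqr|sma)\\(\\)", names(f))
  expect_true(all(abs(f[loc]) < 1e-12))
  expect_true(all(f[grep("entropy", names(f))] == 0))
  expect_true(all(f[grep("correlation", names(f))] == 0))
  expect_true(all(is.finite(f)))
})

test_that("non-finite features are rejected with the offending name", {
  rec <- generate_activity("stand", 3, seed = 8)
  sig <- derive_signals(rec)
  sig$tBodyAcc[5, 1] <- Inf
  expect_error(extract_features(sig, 0), "tBodyAcc")
})

test_that("window labels are majority-vote with earliest-label ties", {
  labels <- c(rep("sit", 60), rep("walk", 68), rep("walk", 200))
  rec <- generate_activity("walk", 3.28, seed = 2)
  rec$labels <- labels
  sig <- derive_signals(rec)
  fw <- extract_features(sig, 0)
  expect_identical(fw$label, "walk")  # 68 walk vs 60 sit

  rec$labels <- c(rep("sit", 64), rep("walk", 64), rep("walk", 200))
  sig <- derive_signals(rec)
  expect_identical(extract_features(sig, 0)$label, "sit")  # tie -> earliest

  # first window mixes three labels: dropped under drop_mixed
  rec$labels <- c(rep("sit", 40), rep("stand", 40), rep("walk", 248))
  rf <- recording_features(rec, drop_mixed = TRUE)
  expect_false(0 %in% rf$starts)
  expect_true(64 %in% rf$starts)
})

test_that("standardization centres and scales training data without leakage", {
  set.seed(31)
  x <- matrix(rnorm(40 * 561, mean = 3, sd = 2), 40, 561)
  x[, 17] <- 5  # constant column
  params <- fit_standardizer(x)
  xs <- apply_standardizer(params, x)
  expect_lt(max(abs(colMeans(xs))), 1e-12)
  sds <- apply(xs[, -17], 2, sd)
  expect_lt(max(abs(sds - 1)), 1e-9)

  # degenerate feature: scale falls back to 1, output 0, flagged
  expect_true(params$degenerate[17])
  expect_equal(params$scale[17], 1)
  expect_true(all(xs[, 17] == 0))

  # train-fit parameters applied to held-out data differ from refitting
  held <- matrix(rnorm(10 * 561, mean = 10), 10, 561)
  via_train <- apply_standardizer(params, held)
  via_refit <- apply_standardizer(fit_standardizer(held), held)
  expect_gt(max(abs(via_train - via_refit)), 1)

  expect_error(fit_standardizer(x[1, , drop = FALSE]), "at least 2")
  expect_error(apply_standardizer(params, x[, 1:10]), "561")
})
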