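test_that("attitude angles reproduce the closed-form axis-aligned and 45-degree cases", {
  a <- attitude_angles(c(0, 0, 1))
  expect_equal(as.numeric(a[c("theta", "psi", "phi")]), c(0, 0, 0))

  a <- attitude_angles(c(1, 0, 0))
  expect_equal(as.numeric(a[c("theta", "psi", "phi")]), c(90, 0, 90))

  a <- attitude_angles(c(0, 1, 0))
  expect_equal(as.numeric(a[c("theta", "psi", "phi")]), c(0, 90, 90))

  a <- attitude_angles(c(1, 0, 1) / sqrt(2))
  expect_equal(as.numeric(a[c("theta", "psi", "phi")]), c(45, 0, 45))

  expect_error(attitude_angles(c(0, 0, 0)), "zero")
  expect_error(attitude_angles(c(1, NA, 0)), "finite")
})

test_that("attitude angles are scale invariant, psi-antisymmetric and bounded", {
  set.seed(12)
  for (i in 1:25) {
    acc <- rnorm(3)
    if (all(acc == 0)) next
    a <- attitude_angles(acc)
    # scaling the vector by any positive factor changes nothing
    a_scaled <- attitude_angles(acc * runif(1, 0.1, 50))
    expect_equal(as.numeric(a), as.numeric(a_scaled), tolerance = 1e-9)
    # negating Y negates psi and leaves phi untouched
    a_neg <- attitude_angles(acc * c(1, -1, 1))
    expect_equal(a_neg[["psi"]], -a[["psi"]], tolerance = 1e-9)
    expect_equal(a_neg[["phi"]], a[["phi"]], tolerance = 1e-12)
    # range invariants of the fixed convention
    expect_true(abs(a[["theta"]]) <= 90 && abs(a[["psi"]]) <= 90)
    expect_true(a[["phi"]] >= 0 && a[["phi"]] <= 90)
  }
})

test_that("the two-policy posture rule classifies the documented cases", {
  rule <- posture_rule()
  expect_identical(assess_posture(c(theta = 0, psi = 0, phi = 85), rule), "good")
  expect_identical(assess_posture(c(theta = 0, psi = 30, phi = 85), rule), "poor")
  expect_identical(assess_posture(c(theta = 0, psi = 0, phi = 45), rule), "poor")

  expect_error(posture_rule(phi_min = 85, phi_max = 80), "phi_min")
})

test_that("tightening the rule never decreases the poor-posture rate", {
  set.seed(8)
  angles <- data.frame(psi = rnorm(400, 0, 15), phi = runif(400, 40, 90))
  rate_of <- function(rule) {
    mean(assess_posture(angles, rule) == "poor")
  }
  base <- rate_of(posture_rule(10, 80, 90))
  expect_gte(rate_of(posture_rule(5, 80, 90)), base)
  expect_gte(rate_of(posture_rule(10, 85, 90)), base)
  expect_gte(rate_of(posture_rule(5, 85, 88)), base)
})

test_that("session statistics and improvement rate follow their definitions", {
  expect_equal(poor_posture_rate(rep("good", 600))$poor_posture_rate, 0)
  expect_equal(poor_posture_rate(rep("poor", 600))$poor_posture_rate, 1)
  half <- poor_posture_rate(rep(c("good", "poor"), 300), sample_rate = 1)
  expect_equal(half$poor_posture_rate, 0.5)
  expect_equal(half$duration, 600)
  expect_error(poor_posture_rate(character(0)), "empty")

  expect_equal(improvement_rate(0.5, 0.5), 0)
  expect_equal(improvement_rate(0.5, 0), 100)
  expect_equal(improvement_rate(0.5, 0.076), 84.8)
  expect_error(improvement_rate(0, 0.1), "zero")
})

test_that("monitor_posture assesses the gravity component of a sitting recording", {
  # upright sit: gravity on X, phi = 90 -> good posture throughout
  rec <- static_recording(n = 800, gdir = c(1, 0, 0))
  out <- monitor_posture(rec)
  expect_equal(nrow(out), 800)
  expect_true(mean(out$posture == "good") > 0.95)

  # laterally tilted 30 degrees: |psi| ~ 30 -> poor
  tilt <- c(cos(30 * pi / 180), sin(30 * pi / 180), 0)
  out2 <- monitor_posture(static_recording(n = 800, gdir = tilt))
  expect_true(mean(out2$posture == "poor") > 0.95)
})
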