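test_that("posture monitoring fires only while sitting, after the debounce", {
  cfg <- engine_config(posture_debounce = 5, sedentary_limit = 1800,
                       refractory = 60)

  # walking: monitoring inactive, no events
  res <- run_intervention(0:120, rep("walk", 121), rep("poor", 121), cfg)
  expect_equal(nrow(res$events), 0)

  # sustained sit + poor: exactly one vibration at t = debounce
  res <- run_intervention(0:6, rep("sit", 7), rep("poor", 7), cfg)
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$t, 5)
  expect_identical(res$events$channel, "vibration")
  expect_identical(res$events$cause, "poor_posture")

  # alternating good/poor every second never accumulates 5 s of poor
  posture <- rep(c("good", "poor"), 30)
  res <- run_intervention(0:59, rep("sit", 60), posture, cfg)
  expect_equal(nrow(res$events), 0)

  # standing up resets the poor-posture clock
  act <- c(rep("sit", 4), "stand", rep("sit", 4))
  res <- run_intervention(0:8, act, rep("poor", 9), cfg)
  expect_equal(nrow(res$events), 0)
})

test_that("prolonged sitting triggers a walk prompt and walking resets the streak", {
  cfg <- engine_config(posture_debounce = 5, sedentary_limit = 60,
                       refractory = 30)
  tt <- 0:299

  res <- run_intervention(tt, rep("sit", 300), rep("good", 300), cfg)
  sed <- res$events[res$events$cause == "prolonged_sedentary", ]
  # streak clock restarts on firing: prompts at t = 60, 120, 180, 240
  expect_equal(sed$t, c(60, 120, 180, 240))
  expect_identical(unique(sed$channel), "notification")

  # a walk break at t = 150 resets the sedentary clock
  act <- rep("sit", 300)
  act[151:160] <- "walk"
  res2 <- run_intervention(tt, act, rep("good", 300), cfg)
  sed2 <- res2$events[res2$events$cause == "prolonged_sedentary", ]
  expect_equal(sed2$t, c(60, 120, 220, 280))
})

test_that("the engine is a pure, replayable state machine with ordered events", {
  set.seed(44)
  n <- 600
  act <- sample(c("sit", "stand", "walk", "lay_down"), n, replace = TRUE,
                prob = c(0.6, 0.15, 0.15, 0.1))
  posture <- sample(c("good", "poor"), n, replace = TRUE)
  cfg <- engine_config(posture_debounce = 3, sedentary_limit = 40,
                       refractory = 20)
  r1 <- run_intervention(seq_len(n), act, posture, cfg)
  r2 <- run_intervention(seq_len(n), act, posture, cfg)
  expect_identical(r1, r2)

  expect_true(all(diff(r1$events$t) > 0) || nrow(r1$events) <= 1)
  # no two same-cause events closer than the refractory
  for (cause in unique(r1$events$cause)) {
    times <- r1$events$t[r1$events$cause == cause]
    if (length(times) > 1) expect_true(all(diff(times) >= cfg$refractory))
  }

  state <- engine_init()
  expect_error({
    s <- intervention_step(state, "sit", "poor", 5, cfg)$state
    intervention_step(s, "sit", "poor", 4, cfg)
  }, "increasing")
})

test_that("event counts are monotone non-increasing in every timing parameter", {
  set.seed(9)
  n <- 900
  act <- rep("sit", n)
  posture <- sample(c("good", "poor"), n, replace = TRUE, prob = c(0.3, 0.7))
  total <- function(cfg) {
    sum(run_intervention(seq_len(n), act, posture, cfg)$counts)
  }
  base <- engine_config(posture_debounce = 3, sedentary_limit = 120,
                        refractory = 20)
  expect_lte(total(engine_config(6, 120, 20)), total(base))
  expect_lte(total(engine_config(3, 240, 20)), total(base))
  expect_lte(total(engine_config(3, 120, 40)), total(base))
  expect_lte(total(engine_config(3, 120, 80)),
             total(engine_config(3, 120, 40)))
})

test_that("a four-block session yields event counts consistent with per-block poor-posture rates", {
  # 10-minute blocks at 1 Hz alternating intervention-off / intervention-on;
  # the off blocks are analysed with the same engine to count what would
  # have fired. Poor-posture rates drop in the on blocks.
  cfg <- engine_config(posture_debounce = 5, sedentary_limit = 3600,
                       refractory = 60)
  block <- function(rate, seed) {
    set.seed(seed)
    sample(c("poor", "good"), 600, replace = TRUE, prob = c(rate, 1 - rate))
  }
  rates <- c(0.9, 0.2, 0.8, 0.15)
  posture <- unlist(lapply(seq_along(rates),
                           function(i) block(rates[i], 100 + i)))
  tt <- seq_len(4 * 600)
  res <- run_intervention(tt, rep("sit", 2400), posture, cfg)
  ev_block <- findInterval(res$events$t, c(0, 600, 1200, 1800) + 0.5)
  counts <- tabulate(ev_block, nbins = 4)
  # high-rate blocks fire; low-rate blocks fire less (or not at all)
  expect_gt(counts[1], counts[2])
  expect_gt(counts[3], counts[4])
  # empty input gives an empty, well-formed event table
  empty <- run_intervention(numeric(0), character(0), character(0), cfg)
  expect_equal(nrow(empty$events), 0)
  expect_equal(sum(empty$counts), 0)
})
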