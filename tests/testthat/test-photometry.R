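test_that("isosbestic correction follows the ratio formula", {
  rec <- twoChannelRecording(trace(0:1, c(2, 4)), trace(0:1, c(1, 2)))
  expect_equal(traceValues(correctIsosbestic(rec)), c(1, 1))

  same <- twoChannelRecording(trace(0:2, c(3, 4, 5)), trace(0:2, c(3, 4, 5)))
  expect_equal(traceValues(correctIsosbestic(same)), c(0, 0, 0))

  bad <- twoChannelRecording(trace(0:1, c(1, 1)), trace(0:1, c(1, 0)))
  expect_error(correctIsosbestic(bad), class = "signalError")
})

test_that("correction is invariant under common multiplicative gain", {
  set.seed(1)
  t <- seq(0, 10, by = 0.01)
  ch465 <- 5 + sin(t) + rnorm(length(t), 0, 0.05)
  ch405 <- 4 + 0.2 * cos(t / 3)
  base <- correctIsosbestic(twoChannelRecording(trace(t, ch465),
                                                trace(t, ch405)))
  for (g in runif(5, 0.1, 30)) {
    scaled <- correctIsosbestic(
      twoChannelRecording(trace(t, g * ch465), trace(t, g * ch405)))
    expect_equal(traceValues(scaled), traceValues(base), tolerance = 1e-12)
  }
})

test_that("decimation mean-bins to approximately 25 samples per second", {
  t <- seq(0, 10 - 1e-3, by = 1e-3)  # 10 s at 1 kHz
  d <- decimateToRate(trace(t, sin(t)), 25)
  expect_equal(length(d), 250)
  expect_equal(traceRate(d), 25)

  already <- trace(seq(0, 1, by = 1 / 25), rep(1, 26), rate = 25)
  expect_identical(decimateToRate(already, 25), already)

  const <- decimateToRate(trace(t, rep(2, length(t))), 25)
  expect_true(all(traceValues(const) == 2))

  slow <- trace(seq(0, 1, by = 0.1), 1:11, rate = 10)
  expect_error(decimateToRate(slow, 25), class = "rateError")
})

test_that("decimation and correction commute on smooth signals", {
  t <- seq(0, 20, by = 1 / 250)
  ch465 <- 5 + sin(t / 3)
  ch405 <- 4 + 0.3 * cos(t / 5)
  rec <- twoChannelRecording(trace(t, ch465), trace(t, ch405))
  a <- decimateToRate(correctIsosbestic(rec), 25)
  b <- correctIsosbestic(twoChannelRecording(
    decimateToRate(rec@ch465, 25), decimateToRate(rec@ch405, 25)))
  expect_lt(max(abs(traceValues(a) - traceValues(b))), 1e-4)
})

test_that("trial alignment z-scores against the baseline and flags exclusions", {
  rate <- 50
  t <- seq(0, 120, by = 1 / rate)
  set.seed(2)
  y <- sin(t / 4) + rnorm(length(t), 0, 0.2)
  trc <- trace(t, y, rate)
  ev <- eventTable(data.frame(
    trial_id = rep(1:2, each = 3),
    event_label = rep(c("accessibility", "seeking_onset", "food_contact"), 2),
    time = c(28, 30, 34,   68, 70, 86),   # trial 2 spans 18 s > 15 s limit
    session_kind = "multi_phase", stringsAsFactors = FALSE))
  tensor <- alignTrials(trc, ev, "seeking_onset", window = c(-10, 10))
  exc <- excludedTrials(tensor)
  expect_false(exc$excluded[1])
  expect_true(exc$excluded[2])
  expect_equal(exc$reason[2], "trial_too_long")

  # included-trial baselines re-Z-score to mean 0, SD 1 within 1e-9
  ax <- timeAxis(tensor)
  base <- ax >= -10 & ax <= -5
  z <- zMatrix(tensor)[1, base]
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)

  # same-length trial in an "other" session is included at 9 s
  ev9 <- mkEvents(1, c("seeking_onset", "food_contact"), c(30, 39), "other")
  expect_false(excludedTrials(
    alignTrials(trc, ev9, "seeking_onset", window = c(-10, 10)))$excluded[1])

  # constant baseline flags degenerate_baseline
  flat <- trace(t, ifelse(t < 30, 1, 1 + pmin(t - 30, 5)), rate)
  evf <- mkEvents(1, "seeking_onset", 30, "other")
  tf <- alignTrials(flat, evf, "seeking_onset", window = c(-10, 10))
  expect_true(excludedTrials(tf)$excluded[1])
  expect_equal(excludedTrials(tf)$reason[1], "degenerate_baseline")
})

test_that("heatmap normalization maps rows to [0, 1]", {
  tens <- mkTensor(rbind(c(0, 2, 4)), axis = c(-1, 0, 1))
  expect_equal(normalizeHeatmap(tens)[1, ], c(0, 0.5, 1))

  const <- mkTensor(rbind(c(5, 5, 5)), axis = c(-1, 0, 1))
  expect_warning(h <- normalizeHeatmap(const),
                 class = "degenerateTrialWarning")
  expect_equal(h[1, ], c(0, 0, 0))

  set.seed(3)
  rnd <- mkTensor(matrix(rnorm(60), 4), axis = seq_len(15))
  h2 <- normalizeHeatmap(rnd)
  expect_true(all(h2 >= 0 & h2 <= 1))
  expect_equal(unname(apply(h2, 1, min)), rep(0, 4))
  expect_equal(unname(apply(h2, 1, max)), rep(1, 4))
})

test_that("window means support paired baseline/response comparisons", {
  axis <- seq(-10, 10, by = 0.1)
  step <- ifelse(axis < 0, 0, 2)
  tens <- mkTensor(rbind(step, rep(0, length(axis))), axis)
  wm <- windowMeanCompare(tens, c(-8, -7), c(9, 10))
  expect_equal(wm$mean_a, c(0, 0))
  expect_equal(wm$mean_b, c(2, 0))
  expect_error(windowMeanCompare(tens, c(-12, -11), c(9, 10)),
               class = "rangeError")
})

test_that("response exceeds baseline on almost all synthetic trials", {
  phot <- genPhotometrySession(synthParams(seed = 4, nTrials = 20,
                                           noiseSd = 0.5))
  corr <- decimateToRate(correctIsosbestic(phot$recording), 25)
  tensor <- alignTrials(corr, phot$events, "seeking_onset",
                        window = c(-10, 10))
  wm <- windowMeanCompare(tensor, c(-10, -9), c(2, 3))
  expect_gt(mean(wm$mean_b > wm$mean_a), 0.9)
})
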