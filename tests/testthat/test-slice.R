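test_that("slice preprocessing trims 2 min and removes the common bleach", {
  sl <- genSliceRecording(synthParams(seed = 10, noiseSd = 0,
                                      bleachSlope = -0.01),
                          nCells = 8, fracResponders = 0)
  n0 <- ncol(craw(sl$mat))
  adj <- preprocessSlice(sl$mat, sl$drug_onset)
  # 10 samples/s: the first 1200 samples are dropped
  expect_equal(n0 - ncol(craw(adj)), 1200)
  expect_true(min(cellTimes(adj)) >= 120)

  # pure common linear bleach, no responders: adjusted traces flat
  slopes <- apply(craw(adj), 1, function(z)
    coef(lm(z ~ cellTimes(adj)))[2])
  expect_lt(max(abs(slopes)), 1e-3)
  expect_lt(max(abs(craw(adj))), 1e-6)

  short <- cellTraceMatrix("a", rbind(1:100), seq(600, 699))
  expect_error(preprocessSlice(short, 720), class = "inputError")
})

test_that("excited calls use the adjusted 4-sigma rule and count percent", {
  sl <- genSliceRecording(synthParams(seed = 11, noiseSd = 0),
                          nCells = 40, fracResponders = 0.5)
  adj <- preprocessSlice(sl$mat, sl$drug_onset)
  exc <- callExcited(adj, sl$drug_onset)
  expect_equal(sum(exc$excited), 20)
  expect_equal(exc$percent_active, 50)
  expect_equal(unname(exc$excited), sl$truth$responder)

  none <- genSliceRecording(synthParams(seed = 12, noiseSd = 0),
                            nCells = 10, fracResponders = 0)
  excn <- callExcited(preprocessSlice(none$mat, none$drug_onset),
                      none$drug_onset)
  expect_equal(excn$percent_active, 0)
})

test_that("percent active grows monotonically as the threshold drops", {
  sl <- genSliceRecording(synthParams(seed = 13, noiseSd = 0.3,
                                      bleachSlope = -0.01),
                          nCells = 30, fracResponders = 0.4)
  adj <- preprocessSlice(sl$mat, sl$drug_onset)
  pct <- vapply(c(6, 4, 2, 1), function(s)
    callExcited(adj, sl$drug_onset, analysisConfig(sigma_threshold = s)
                )$percent_active, numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("sIPSC metrics report rates, amplitudes and percent of baseline", {
  rec <- sipscRecord("n1", "NPY",
                     eventTimes = c(seq(5, 59, by = 10), seq(65, 115, by = 20)),
                     amplitudes = rep(30, 9),
                     baselineWindow = c(0, 60), analysisWindow = c(60, 120))
  m <- sipscMetrics(rec)
  expect_equal(m$baseline_freq, 6 / 60)
  expect_equal(m$window_freq, 3 / 60)
  expect_equal(m$norm_freq_pct, 50)
  expect_equal(m$norm_amp_pct, 100)   # amplitudes unchanged

  # identical pre/post trains: 100% of baseline
  rec2 <- sipscRecord("n2", "ACSF", c(seq(1, 59, 2), seq(61, 119, 2)),
                      rep(25, 60), c(0, 60), c(60, 120))
  m2 <- sipscMetrics(rec2)
  expect_equal(m2$norm_freq_pct, 100)
  expect_equal(m2$norm_amp_pct, 100)

  empty <- sipscRecord("n3", "NPY", c(70, 80), c(10, 10),
                       c(0, 60), c(60, 120))
  expect_error(sipscMetrics(empty), class = "metricError")
})

test_that("sIPSC metrics do not depend on input event order", {
  set.seed(14)
  times <- sort(runif(40, 0, 120))
  amps <- runif(40, 10, 60)
  shuf <- sample(40)
  a <- sipscMetrics(sipscRecord("n", "NPY", times, amps,
                                c(0, 60), c(60, 120)))
  b <- sipscMetrics(sipscRecord("n", "NPY", times[shuf], amps[shuf],
                                c(0, 60), c(60, 120)))
  expect_equal(a, b)
})

test_that("inclusion requires >5 Hz baseline and a stable control period", {
  lowRate <- sipscRecord("n", "ACSF", seq(0.125, 60, by = 0.25)[1:240],
                         rep(20, 240), c(0, 60), c(60, 120))  # 4 Hz
  r <- sipscInclusion(lowRate, controlChange = 5)
  expect_false(r$include)
  expect_equal(r$reason, "low_rate")

  hiRate <- sipscRecord("n", "ACSF", seq(0, 59.9, by = 1 / 6),
                        rep(20, 360), c(0, 60), c(60, 120))   # 6 Hz
  expect_false(sipscInclusion(hiRate, controlChange = 25)$include)
  expect_equal(sipscInclusion(hiRate, controlChange = 25)$reason, "unstable")
  expect_true(sipscInclusion(hiRate, controlChange = 5)$include)
})
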