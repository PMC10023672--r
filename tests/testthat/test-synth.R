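test_that("generators are deterministic for a fixed seed", {
  p <- synthParams(seed = 42, nTrials = 3)
  a <- genPhotometrySession(p)
  b <- genPhotometrySession(p)
  expect_identical(traceValues(a$recording@ch465),
                   traceValues(b$recording@ch465))
  expect_identical(a$truth, b$truth)

  pa <- genPoseSession(p, nBouts = 2, durationS = 20)
  pb <- genPoseSession(p, nBouts = 2, durationS = 20)
  expect_identical(pa$bottom@coords, pb$bottom@coords)

  ca <- genCountMatrix(p, nCells = 30, nLowUmi = 2, nHighMito = 2)
  cb <- genCountMatrix(p, nCells = 30, nLowUmi = 2, nHighMito = 2)
  expect_identical(ca$counts, cb$counts)
})

test_that("noise-free photometry sessions have a clean isosbestic channel", {
  p <- synthParams(seed = 1, nTrials = 2, noiseSd = 0, artifactGain = 0,
                   bleachSlope = 0)
  s <- genPhotometrySession(p, rate = 200)
  expect_equal(diff(range(traceValues(s$recording@ch405))), 0)
  corr <- correctIsosbestic(s$recording)
  # corrected trace is the scaled activity: flat before the first onset,
  # active after it
  before <- traceTimes(corr) < min(s$truth$neural_onset)
  expect_lt(max(abs(traceValues(corr)[before])), 1e-12)
  expect_gt(max(traceValues(corr)), 0.4)
})

test_that("stored latencies average to the configured onset lead", {
  s <- genPhotometrySession(synthParams(seed = 2, nTrials = 50))
  expect_equal(nrow(s$truth), 50)
  expect_equal(mean(s$truth$seek_onset - s$truth$neural_onset), 6,
               tolerance = 0.1)
  # empty session is not an error
  e <- genPhotometrySession(synthParams(seed = 3, nTrials = 0))
  expect_equal(nrow(e$truth), 0)
  expect_equal(nrow(eventData(e$events)), 0)
})

test_that("endoscope populations follow the requested class proportions", {
  pop <- genEndoscopePopulation(synthParams(seed = 5), nCells = 100)
  expect_equal(sum(pop$truth$class == "seeking"), 25)
  expect_equal(sum(pop$truth$class == "consummatory"), 39)
  expect_equal(nrow(craw(pop$food$mat)), 100)

  only <- genEndoscopePopulation(
    synthParams(seed = 6, noiseSd = 0,
                classProportions = c(seeking = 1, consummatory = 0,
                                     ambiguous = 0, non_responsive = 0)),
    nCells = 5)
  # all cells fall silent after food contact (tail of the kernel aside)
  t <- cellTimes(only$food$mat)
  ev <- eventData(only$food$events)
  contact1 <- ev$time[ev$trial_id == 1 & ev$event_label == "food_contact"]
  end1 <- ev$time[ev$trial_id == 1 & ev$event_label == "consumption_end"]
  late <- t > contact1 + 3 & t < end1
  early <- t > contact1 - 2 & t <= contact1
  expect_lt(max(craw(only$food$mat)[, late]),
            min(craw(only$food$mat)[, early]))
})

test_that("pose sessions script exactly the requested bouts", {
  none <- genPoseSession(synthParams(seed = 7, noiseSd = 0), nBouts = 0)
  expect_equal(sum(none$labels), 0)
  expect_equal(nrow(none$bouts), 0)

  three <- genPoseSession(synthParams(seed = 8, noiseSd = 0), nBouts = 3)
  expect_equal(nrow(three$bouts), 3)
  expect_equal(sum(three$labels), 3 * 36)
})

test_that("slice recordings expose responders and a common bleach", {
  sl <- genSliceRecording(synthParams(seed = 9, noiseSd = 0), nCells = 6,
                          fracResponders = 0.5)
  expect_equal(sum(sl$truth$responder), 3)
  expect_equal(sl$drug_onset, 720)
})

test_that("count-matrix generation validates its designations", {
  expect_error(genCountMatrix(synthParams(seed = 1), nCells = 4,
                              nLowUmi = 3, nHighMito = 2),
               class = "parameterError")
  cm <- genCountMatrix(synthParams(seed = 10), nCells = 20, nLowUmi = 2,
                       nHighMito = 1)
  st <- countMatrixQcStats(cm$counts)
  expect_true(all(st$umi[cm$truth$status == "low_umi"] < 500))
  expect_true(all(st$mito[cm$truth$status == "high_mito"] > 0.4))
  expect_true(all(st$umi[cm$truth$status == "clean"] >= 500))
  expect_true(all(st$mito[cm$truth$status != "high_mito"] <= 0.4))
})
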