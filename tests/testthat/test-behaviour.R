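mkSimpleTrack <- function(view = "bottom", n = 10, lik = 1) {
  pose <- genPoseSession(synthParams(seed = 1, noiseSd = 0), nBouts = 0,
                         durationS = n / 24)
  tr <- pose[[view]]
  tr@coords[, , 3] <- lik
  tr
}

test_that("likelihood filtering interpolates low-confidence points", {
  tr <- mkSimpleTrack(n = 10)
  tr@coords[, "snout", 1] <- 1:10
  tr@coords[, "snout", 2] <- 2 * (1:10)
  tr@coords[5, "snout", ] <- c(999, -999, 0.85)
  f <- filterLikelihood(tr)
  expect_equal(f@coords[5, "snout", 1], 5)     # linear between frames 4 and 6
  expect_equal(f@coords[5, "snout", 2], 10)
  expect_true(f@interpolated[5, "snout"])
  expect_equal(sum(f@interpolated), 1)

  # all confident: unchanged
  tr2 <- mkSimpleTrack(n = 10)
  f2 <- filterLikelihood(tr2)
  expect_equal(f2@coords, tr2@coords)

  # leading/trailing gaps hold the nearest confident value
  tr3 <- mkSimpleTrack(n = 6)
  tr3@coords[, "snout", 1] <- c(50, 1, 2, 3, 4, 60)
  tr3@coords[c(1, 6), "snout", 3] <- 0.1
  f3 <- filterLikelihood(tr3)
  expect_equal(f3@coords[1, "snout", 1], 1)
  expect_equal(f3@coords[6, "snout", 1], 4)

  # a bodypart with no confident frame at all is a track error
  tr4 <- mkSimpleTrack(n = 6)
  tr4@coords[, "tail_base", 3] <- 0.5
  expect_error(filterLikelihood(tr4), "tail_base", class = "trackError")
})

test_that("the three posture criteria encode the printed geometry", {
  pose <- genPoseSession(synthParams(seed = 2, noiseSd = 0), nBouts = 1,
                         durationS = 10)
  crit <- evaluateCriteria(pose$bottom, pose$side)
  expect_equal(unname(crit[, "c1"] & crit[, "c2"] & crit[, "c3"]),
               pose$labels)
  # outside bouts each criterion is individually violated by construction
  out <- !pose$labels
  expect_true(all(!crit[out, "c1"]))
  expect_true(all(!crit[out, "c2"]))
  expect_true(all(!crit[out, "c3"]))

  # c3 needs the snout inside the zone in BOTH views
  tweaked <- pose$side
  tweaked@coords[, "snout", 1] <- 1   # far outside the side zone
  crit2 <- evaluateCriteria(pose$bottom, tweaked)
  expect_true(all(!crit2[, "c3"]))

  degen <- pose$side
  degen@foodZone <- cbind(c(1, 1, 1), c(2, 2, 2))
  expect_error(evaluateCriteria(pose$bottom, degen),
               class = "geometryError")
})

test_that("criteria are invariant to paw swaps, translation and scaling", {
  pose <- genPoseSession(synthParams(seed = 3, noiseSd = 1), nBouts = 2,
                         durationS = 20)
  crit <- evaluateCriteria(pose$bottom, pose$side)

  swap <- pose$bottom
  swap@coords[, c("front_paw_L", "front_paw_R"), ] <-
    swap@coords[, c("front_paw_R", "front_paw_L"), ]
  swap@coords[, c("hind_paw_L", "hind_paw_R"), ] <-
    swap@coords[, c("hind_paw_R", "hind_paw_L"), ]
  critSwap <- evaluateCriteria(swap, pose$side)
  expect_equal(critSwap[, c("c1", "c2")], crit[, c("c1", "c2")])

  shift <- pose$bottom
  shift@coords[, , 1] <- shift@coords[, , 1] + 37
  shift@coords[, , 2] <- shift@coords[, , 2] - 12
  shift@foodZone <- sweep(shift@foodZone, 2, c(-37, 12))
  critShift <- evaluateCriteria(shift, pose$side)
  expect_equal(critShift, crit)

  scale <- pose$bottom
  scale@coords[, , 1:2] <- scale@coords[, , 1:2] * 2.5
  critScale <- evaluateCriteria(scale, pose$side)
  expect_equal(critScale[, c("c1", "c2")], crit[, c("c1", "c2")])
})

test_that("frame labelling is the conjunction of the criteria", {
  pose <- genPoseSession(synthParams(seed = 4, noiseSd = 0), nBouts = 2,
                         durationS = 30)
  labels <- labelConsummatoryFrames(pose$bottom, pose$side)
  expect_equal(labels, pose$labels)

  shortSide <- pose$side
  shortSide@coords <- pose$side@coords[1:10, , , drop = FALSE]
  shortSide@interpolated <- pose$side@interpolated[1:10, , drop = FALSE]
  expect_error(labelConsummatoryFrames(pose$bottom, shortSide),
               class = "syncError")
})

test_that("bout segmentation merges gaps and enforces minimum duration", {
  labels <- as.logical(c(1, 1, 1, 0, 0, 1, 1, 1, 0))
  b0 <- extractBouts(labels, fps = 24, minDuration = 2, maxGap = 0)
  expect_equal(nrow(b0), 2)
  expect_equal(b0$onset_frame, c(1, 6))
  expect_equal(b0$offset_frame, c(3, 8))
  expect_equal(b0$duration, c(3, 3) / 24)

  b2 <- extractBouts(labels, fps = 24, minDuration = 2, maxGap = 2)
  expect_equal(nrow(b2), 1)
  expect_equal(c(b2$onset_frame, b2$offset_frame), c(1, 8))

  expect_equal(nrow(extractBouts(rep(FALSE, 20))), 0)

  # conservation: with no merging or minimum, bout frames = true frames
  set.seed(5)
  rnd <- runif(500) < 0.3
  bt <- extractBouts(rnd, minDuration = 1, maxGap = 0)
  expect_equal(sum(bt$offset_frame - bt$onset_frame + 1), sum(rnd))
})

test_that("success rate is S2 over S1 + S2", {
  expect_equal(successRate(2, 8), 0.8)
  expect_equal(successRate(0, 5), 1)
  expect_equal(successRate(5, 5), 0.5)
  expect_error(successRate(0, 0), class = "parameterError")
  expect_error(successRate(-1, 3), class = "parameterError")
})
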