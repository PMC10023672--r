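test_that("cell Z-scoring uses baseline statistics and trial-length limits", {
  rate <- 10
  t <- seq(0, 60, by = 1 / rate)
  # baseline mean 10, SD 2 (alternating +-2), value 18 after onset -> Z = 4
  base <- 10 + 2 * rep(c(1, -1), length.out = length(t))
  y <- ifelse(t < 30, base, 18)
  mat <- cellTraceMatrix("a", rbind(y), t)
  ev <- mkEvents(1, c("seeking_onset", "food_contact"), c(30, 35),
                 "endoscope")
  zarr <- zscoreCells(mat, ev, window = c(-10, 15))
  ax <- zarr@timeAxis
  zAt5 <- zarr@z[1, 1, which.min(abs(ax - 5))]
  bsel <- ax >= -10 & ax <= -5
  yi <- approx(t, y, xout = 30 + ax)$y
  expect_equal(zAt5, (18 - mean(yi[bsel])) / sd(yi[bsel]), tolerance = 1e-9)

  # endoscope trial spanning 26 s is excluded
  ev26 <- mkEvents(1, c("seeking_onset", "consumption_end"), c(30, 56),
                   "endoscope")
  zarr26 <- zscoreCells(mat, ev26, window = c(-10, 15))
  expect_true(zarr26@excluded$excluded[1])
  expect_equal(zarr26@excluded$reason[1], "trial_too_long")

  # constant cell is flagged degenerate
  matc <- cellTraceMatrix("a", rbind(rep(1, length(t))), t)
  zc <- zscoreCells(matc, ev, window = c(-10, 15))
  expect_true(zc@degenerate[1, 1])
})

test_that("responsiveness uses a strict 4-sigma threshold", {
  cfg <- analysisConfig()
  expect_true(callResponsive(mkZArray(5.0), cfg)$responsive)
  expect_false(callResponsive(mkZArray(4.0), cfg)$responsive)  # boundary
  expect_false(callResponsive(mkZArray(3.9), cfg)$responsive)
})

test_that("food-specificity labels partition the response patterns", {
  lab <- function(p) classifyFoodSpecificity(mkCalls(p))$label
  expect_equal(lab(c(TRUE, TRUE, TRUE, FALSE)), "food_specific")
  expect_equal(lab(c(TRUE, TRUE, TRUE, TRUE)), "non_specific")
  expect_equal(lab(c(FALSE, FALSE, FALSE, TRUE)), "non_food_specific")
  expect_equal(lab(c(FALSE, FALSE, FALSE, FALSE)), "non_responsive")
  expect_equal(lab(c(TRUE, FALSE, TRUE, FALSE)), "unclassified")

  # every one of the 16 patterns gets exactly one of the five labels
  labs <- vapply(0:15, function(k)
    lab(as.logical(bitwAnd(k, c(8, 4, 2, 1)))), character(1))
  expect_true(all(labs %in% c("food_specific", "non_specific",
                              "non_food_specific", "non_responsive",
                              "unclassified")))

  expect_error(classifyFoodSpecificity(mkCalls(rep(TRUE, 4))[-1, ]),
               class = "inputError")
})

test_that("NF0 normalization is bounded and affine-invariant", {
  mat <- cellTraceMatrix(c("a", "b"), rbind(c(1, 3, 5), c(2, 2, 4)), 0:2)
  nf <- nf0Normalize(mat)
  expect_equal(nf$nf0[1, ], c(0, 0.5, 1))
  expect_true(all(nf$nf0 >= 0 & nf$nf0 <= 1, na.rm = TRUE))

  matT <- cellTraceMatrix(c("a", "b"), 3.7 * craw(mat) + 11, 0:2)
  expect_equal(nf0Normalize(matT)$nf0, nf$nf0, tolerance = 1e-12)

  matc <- cellTraceMatrix("a", rbind(c(2, 2, 2)), 0:2)
  nfc <- nf0Normalize(matc)
  expect_true(nfc$degenerate[["a"]])
  expect_true(all(is.na(nfc$nf0)))
})

test_that("phase scores follow the NF0-at-event definitions", {
  # piecewise-linear NF0 with known values at contact and trial end
  t <- seq(0, 40, by = 0.1)
  nf0F <- rbind(approx(c(0, 20, 25, 30, 40), c(0, 0, 0.8, 0.9, 0),
                       xout = t)$y)
  nf0N <- rbind(approx(c(0, 20, 25, 30, 40), c(0, 0, 0.6, 0.2, 0),
                       xout = t)$y)
  evF <- mkEvents(1, c("seeking_onset", "food_contact", "consumption_end"),
                  c(20, 25, 30), "endoscope")
  evN <- mkEvents(1, c("seeking_onset", "food_contact", "food_zone_exit"),
                  c(20, 25, 30), "endoscope")
  sc <- phaseScores(nf0F, t, evF, nf0N, t, evN, "a")
  expect_equal(sc$s1, 0.8)
  expect_equal(sc$s2, 0.6)
  expect_equal(sc$c, 0.9 - 0.8, tolerance = 1e-12)

  # flat trace in the food session: consummatory score 0
  nf0flat <- rbind(rep(0.5, length(t)))
  scf <- phaseScores(nf0flat, t, evF, nf0N, t, evN, "a")
  expect_equal(scf$c, 0)
})

test_that("the phase rule applies strict inequalities with an NF0 0.4 cut", {
  cls <- function(s1, s2, c) classifyPhase(
    data.frame(cell_id = "a", s1 = s1, s2 = s2, c = c, status = "ok"),
    responsive = TRUE)$label
  expect_equal(cls(0.8, 0.6, 0.1), "seeking")
  expect_equal(cls(0.8, 0.3, 0.1), "consummatory")   # s2 below 0.4
  expect_equal(cls(0.1, 0.6, 0.8), "consummatory")   # c exceeds s1
  expect_equal(cls(0.5, 0.4, 0.5), "ambiguous")      # both ties
  expect_equal(cls(0.5, 0.6, 0.5), "ambiguous")      # s1 == c
  expect_equal(classifyPhase(
    data.frame(cell_id = "a", s1 = 0.8, s2 = 0.6, c = 0.1, status = "ok"),
    responsive = FALSE)$label, "non_responsive")
})

test_that("population proportions sum to one and match the counts", {
  labels <- c(rep("seeking", 12), rep("consummatory", 19),
              rep("non_responsive", 17))
  pr <- populationProportions(labels)
  expect_equal(sum(pr$fraction), 1)
  expect_equal(pr$fraction[pr$label == "seeking"], 12 / 48)
  expect_equal(round(100 * pr$fraction[pr$label == "consummatory"], 1), 39.6)
  expect_equal(populationProportions(rep("seeking", 5))$fraction, 1)
})

test_that("noiseless populations are recovered exactly, including ties", {
  pop <- genEndoscopePopulation(
    synthParams(seed = 8, noiseSd = 0,
                classProportions = c(seeking = 0.3, consummatory = 0.3,
                                     ambiguous = 0.2, non_responsive = 0.2)),
    nCells = 20)
  res <- classifyPopulation(pop)
  expect_equal(res$scores$label, pop$truth$class)
})

test_that("phase scores are invariant under affine transforms of Craw", {
  pop <- genEndoscopePopulation(synthParams(seed = 9, noiseSd = 0.2),
                                nCells = 10)
  res <- classifyPopulation(pop)
  aff <- function(m) cellTraceMatrix(cellIds(m), 2.5 * craw(m) - 40,
                                     cellTimes(m))
  popT <- pop
  popT$food$mat <- aff(pop$food$mat)
  popT$nofood$mat <- aff(pop$nofood$mat)
  resT <- classifyPopulation(popT)
  expect_equal(resT$scores$s1, res$scores$s1, tolerance = 1e-9)
  expect_equal(resT$scores$s2, res$scores$s2, tolerance = 1e-9)
  expect_equal(resT$scores$c, res$scores$c, tolerance = 1e-9)
  expect_equal(resT$scores$label, res$scores$label)
})
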