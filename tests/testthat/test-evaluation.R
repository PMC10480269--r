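test_that("percent uncertainty follows its defining arithmetic", {
  expect_equal(absoluteUncertainty(0.3291, 0.3291), 0)
  expect_equal(absoluteUncertainty(0.34, 0.3291),
               100 * abs(0.34 - 0.3291) / 0.3291)
  expect_equal(absoluteUncertainty(0.34, 0.3291), 3.312064, tolerance = 1e-6)
  # the human-rate example: 24.08 vs 24 bpm
  expect_equal(absoluteUncertainty(24.08, 24), 1 / 3, tolerance = 1e-9)
  expect_error(absoluteUncertainty(0.3, 0), "positive")
})

test_that("percent uncertainty is scale-invariant and non-negative", {
  withr::local_seed(4)
  e <- runif(50, 0.05, 3)
  t <- runif(50, 0.05, 3)
  u <- absoluteUncertainty(e, t)
  expect_true(all(u >= 0))
  for (k in c(0.01, 60, 1e3))
    expect_equal(absoluteUncertainty(k * e, k * t), u, tolerance = 1e-9)
})

test_that("rate classification uses the closed normal band", {
  expect_equal(classifyRate(0.3291), "normal")
  expect_equal(classifyRate(0.06993), "abnormal")
  expect_equal(classifyRate(c(0.1, 1.0)), c("normal", "normal"))
  expect_equal(classifyRate(1.0000001), "abnormal")
  expect_error(classifyRate(0.5, normalBand = c(1, 0.1)), "increasing")
  expect_error(classifyRate(-0.2), "positive")
})

test_that("grid frequencies classify exactly into the flagged partition", {
  g <- calibrationGrid()
  cls <- classifyRate(g$frequency_hz)
  expect_equal(cls == "abnormal", g$is_abnormal)
  expect_equal(sum(cls == "abnormal"), 7L)
})

test_that("confusion metrics derive exactly from the counts", {
  g <- calibrationGrid()
  truth <- ifelse(g$is_abnormal, "abnormal", "normal")
  perfect <- confusionMetrics(truth, truth)
  expect_equal(confusionCounts(perfect),
               c(tp = 7L, fp = 0L, tn = 28L, fn = 0L))
  expect_equal(sensitivity(perfect), 1)
  expect_equal(specificity(perfect), 1)
  expect_equal(positivePredictivity(perfect), 1)
  expect_equal(accuracy(perfect), 1)

  allNormal <- confusionMetrics(rep("normal", 35), truth)
  expect_equal(sensitivity(allNormal), 0)
  expect_equal(specificity(allNormal), 1)
  expect_true(is.na(positivePredictivity(allNormal)))

  # no abnormal cases at all: sensitivity is undefined, not zero
  noneTrue <- confusionMetrics(rep("normal", 5), rep("normal", 5))
  expect_true(is.na(sensitivity(noneTrue)))
  expect_equal(specificity(noneTrue), 1)

  expect_error(confusionMetrics("normal", c("normal", "abnormal")),
               "equal length")
  expect_error(confusionMetrics("maybe", "normal"), "labels")
})

test_that("a small grid run is reproducible and internally consistent", {
  rep1 <- runGrid(repeats = 1, noise = NoiseModel(), seed = 7,
                  duration = 30, cfg = smallCfg())
  rep2 <- runGrid(repeats = 1, noise = NoiseModel(), seed = 7,
                  duration = 30, cfg = smallCfg())
  expect_identical(gridResults(rep1), gridResults(rep2))
  res <- gridResults(rep1)
  expect_equal(nrow(res), 35L)
  expect_equal(overallUncertainty(rep1), mean(res$uncertainty_pct))
  pd <- displacementSummary(rep1)
  expect_equal(nrow(pd), 5L)
  expect_equal(sum(pd$n), 35L)
  expect_equal(pd$mean_uncertainty_pct[pd$step_cm == 2],
               mean(res$uncertainty_pct[res$step_cm == 2]))
  # a different seed draws different noise
  rep3 <- runGrid(repeats = 1, noise = NoiseModel(), seed = 8,
                  duration = 30, cfg = smallCfg())
  expect_false(identical(gridResults(rep3)$estimated_hz, res$estimated_hz))
})

test_that("mean grid uncertainty does not improve as read noise grows", {
  # reduced sweep: 7 conditions x several seeds at three read-noise levels
  g <- calibrationGrid()[seq(1, 35, by = 5), ]
  meanUnc <- function(readSd, seeds) {
    mean(vapply(seeds, function(s) {
      u <- mapply(function(f, d, cond) {
        nm <- NoiseModel(readNoiseSd = readSd, shotNoiseScale = 0,
                         driftAmplitude = 0,
                         seed = as.integer(s * 1000 + cond))
        sp <- simulateAcquisition(MotionSpec(f, displacement = d,
                                             duration = 30),
                                  cfg = smallCfg(), noise = nm)
        absoluteUncertainty(estimatedHz(recoverRate(sp)), f)
      }, g$frequency_hz, g$step_cm, seq_len(nrow(g)))
      mean(u)
    }, numeric(1)))
  }
  seeds <- 1:10
  m <- vapply(c(0, 2000, 20000), meanUnc, numeric(1), seeds = seeds)
  # non-decreasing within sampling slack; the extremes must separate clearly
  expect_lt(m[1], m[3])
  expect_lt(m[2], m[3] * 1.1 + 0.05)
  expect_lt(m[1], m[2] * 1.1 + 0.05)
})

test_that("grid reports serialize to the two delimited tables", {
  rep1 <- runGrid(repeats = 1, noise = zeroNoise(), seed = 1,
                  duration = 20, cfg = smallCfg())
  dir <- withr::local_tempdir()
  files <- writeGridReport(rep1, dir)
  expect_true(all(file.exists(files)))
  back <- utils::read.table(files[1], sep = "\t", header = TRUE)
  expect_equal(nrow(back), 35L)
  expect_equal(back$uncertainty_pct, gridResults(rep1)$uncertainty_pct)
  summLines <- readLines(files[2])
  expect_true(any(grepl("overall_mean_uncertainty_pct", summLines)))
  expect_true(any(grepl("positive_predictivity", summLines)))
})
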