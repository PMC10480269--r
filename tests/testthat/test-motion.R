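test_that("sampled sine displacement matches the closed form", {
  spec <- MotionSpec(frequency = 0.25, displacement = 2, duration = 8)
  ds <- displacementSeries(spec, sampleRate = 10)
  expect_equal(nrow(ds), 80L)
  # t = 1 s is a quarter period: full positive amplitude (= displacement/2)
  expect_equal(ds$displacement_cm[ds$time_s == 1], 1.0)
  # t = 0 with zero phase starts at mid-travel
  expect_equal(ds$displacement_cm[1], 0)
  expect_equal(ds$displacement_cm,
               1 * sin(2 * pi * 0.25 * ds$time_s))
})

test_that("long records reach the displacement extrema", {
  spec <- MotionSpec(frequency = 0.3291, displacement = 2, duration = 600)
  ds <- displacementSeries(spec, sampleRate = 10)
  expect_equal(nrow(ds), 6000L)
  # one-sample slack on hitting the turning points
  slack <- 2 * pi * spec@frequency * 1 / 10
  expect_lt(abs(max(ds$displacement_cm) - 1), slack)
  expect_lt(abs(min(ds$displacement_cm) + 1), slack)
})

test_that("displacement series is periodic and spans the peak-to-peak range", {
  for (wf in c("sine", "triangle")) {
    spec <- MotionSpec(frequency = 0.5, displacement = 3, waveform = wf,
                       phase = 1.1, duration = 20)
    ds <- displacementSeries(spec, sampleRate = 20)
    # values one period apart agree (period is a whole number of samples)
    lag <- 20 / 0.5
    v <- ds$displacement_cm
    expect_equal(v[seq_len(length(v) - lag)], v[-seq_len(lag)],
                 tolerance = 1e-12)
    # peak-to-peak range within the sampling slack of the nominal travel
    maxSlope <- 2 * pi * 0.5 * 1.5
    expect_lt(abs(diff(range(v)) - 3), 2 / 20 * maxSlope)
  }
})

test_that("sampling below Nyquist is rejected, naming both rates", {
  spec <- MotionSpec(frequency = 2.286, displacement = 1)
  expect_error(displacementSeries(spec, sampleRate = 4), "4.*2.286|2.286.*4")
  expect_error(simulateAcquisition(spec, cfg = smallCfg(sampleRate = 4),
                                   noise = zeroNoise()),
               "Nyquist")
})

test_that("motion specs are validated", {
  expect_error(MotionSpec(frequency = -1), "frequency")
  expect_error(MotionSpec(0.5, displacement = 0), "displacement")
  expect_error(MotionSpec(0.5, phase = 7), "phase")
  expect_error(MotionSpec(0.5, waveform = "square"), "waveform")
})

test_that("the embedded grid matches the stage calibration table", {
  g <- calibrationGrid()
  expect_equal(nrow(g), 35L)
  expect_equal(g$frequency_hz[g$rpm == 10 & g$step_cm == 1], 0.333)
  expect_equal(g$frequency_hz[g$rpm == 20 & g$step_cm == 2], 0.3291)
  expect_equal(sum(g$is_abnormal), 7L)
  expect_equal(max(g$frequency_hz), 2.286)
  expect_setequal(g$frequency_hz[g$is_abnormal],
                  c(0.07683, 0.06993, 1.31, 1.6, 1.861, 2.286, 1.111))
})

test_that("nominal kinematic frequency is linear in rpm and approximate", {
  expect_equal(nominalFrequency(10, 1, 4), 1 / 3, tolerance = 1e-12)
  # doubling rpm doubles the frequency
  expect_equal(nominalFrequency(34, 2.5, 4), 2 * nominalFrequency(17, 2.5, 4))
  # the kinematic model deviates from the measured grid in some cells
  expect_equal(nominalFrequency(10, 4, 4), 0.0833, tolerance = 1e-3)
  expect_false(isTRUE(all.equal(nominalFrequency(10, 4, 4), 0.07683,
                                tolerance = 0.01)))
  expect_error(nominalFrequency(-10, 1), "positive")
})

test_that("the grid round-trips through its delimited form", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGrid(calibrationGrid(), path)
  header <- readLines(path, n = 1)
  expect_match(header, "rpm\tstep_cm\tfrequency_hz\tis_abnormal")
  g2 <- readGrid(path)
  expect_equal(g2, calibrationGrid())
})
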