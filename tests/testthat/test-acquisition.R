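test_that("a rendered frame is baseline plus a scaled laser line", {
  cfg <- SpectrometerConfig()
  spot <- LaserSpot()
  # zero reflected light: flat baseline
  expect_equal(renderFrame(0, cfg, spot),
               rep(150, length(cfg@wavelengthGrid)))
  # full reflection: peak bin = baseline + integrationScale at the bin
  # nearest the line centre
  fr <- renderFrame(1, cfg, spot)
  k <- which.min(abs(cfg@wavelengthGrid - 632.8))
  expect_equal(which.max(fr), k)
  expect_equal(max(fr), 150 + 10000 * max(exp(-4 * log(2) *
    ((cfg@wavelengthGrid[k] - 632.8) / 1.5)^2)))
  expect_true(all(fr > 0))
})

test_that("background-subtracted frame area is linear in reflected fraction", {
  cfg <- smallCfg(512)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  areas <- vapply(c(0.25, 0.5, 1.0), function(refl)
    trapz(cfg@wavelengthGrid, renderFrame(refl, cfg) - cfg@baseline),
    numeric(1))
  slopes <- areas / c(0.25, 0.5, 1.0)
  expect_equal(slopes[1], slopes[2], tolerance = 1e-9)
  expect_equal(slopes[2], slopes[3], tolerance = 1e-9)
})

test_that("a grid not covering the laser line is rejected", {
  cfg <- SpectrometerConfig(wavelengthGrid = seq(700, 900, length.out = 64))
  expect_error(renderFrame(0.5, cfg, LaserSpot()), "does not cover")
})

test_that("acquisition has the contracted shape and periodicity", {
  spec <- MotionSpec(0.3291, displacement = 2, duration = 60)
  sp <- simulateAcquisition(spec, cfg = smallCfg(), noise = zeroNoise())
  expect_s4_class(sp, "TimeResolvedSpectra")
  expect_equal(ncol(sp), 600L)         # floor(60 x 10) frames
  expect_equal(nrow(sp), 128L)
  # the 632 nm section of the noiseless run is periodic at 1/f
  w <- intensities(extractWaveform(sp))
  period <- 1 / 0.3291
  tm <- timeAxis(sp)
  interp <- stats::approx(tm, w, xout = tm + period)$y
  keep <- !is.na(interp)
  # RMS mismatch after one period, relative to the modulation depth; the
  # comparison interpolates linearly between samples, which dominates the
  # residual at the dip edges
  d <- (interp[keep] - w[keep]) / diff(range(w))
  expect_lt(sqrt(mean(d^2)), 0.05)

  # a period that is a whole number of samples shifts exactly
  sp4 <- simulateAcquisition(MotionSpec(0.25, displacement = 2,
                                        duration = 20),
                             cfg = smallCfg(), noise = zeroNoise())
  w4 <- intensities(extractWaveform(sp4))
  expect_equal(w4[seq_len(length(w4) - 40)], w4[-seq_len(40)],
               tolerance = 1e-9)
})

test_that("noiseless pipeline is deterministic; seeded noise is bit-stable", {
  spec <- MotionSpec(0.4828, displacement = 2, duration = 20)
  a <- simulateAcquisition(spec, cfg = smallCfg(), noise = zeroNoise())
  b <- simulateAcquisition(spec, cfg = smallCfg(), noise = zeroNoise())
  expect_identical(intensities(a), intensities(b))

  nm <- NoiseModel(seed = 77L)
  c1 <- simulateAcquisition(spec, cfg = smallCfg(), noise = nm)
  c2 <- simulateAcquisition(spec, cfg = smallCfg(), noise = nm)
  expect_identical(intensities(c1), intensities(c2))
  expect_false(identical(intensities(a), intensities(c1)))
  # a different seed gives a different draw
  nm2 <- NoiseModel(seed = 78L)
  expect_false(identical(
    intensities(simulateAcquisition(spec, cfg = smallCfg(), noise = nm2)),
    intensities(c1)))
})

test_that("seeded noise leaves the caller's RNG stream untouched", {
  spec <- MotionSpec(0.5, displacement = 1, duration = 5)
  set.seed(5)
  before <- runif(1)
  set.seed(5)
  invisible(simulateAcquisition(spec, cfg = smallCfg(),
                                noise = NoiseModel(seed = 9L)))
  expect_identical(runif(1), before)
})

test_that("zero noise model returns the input unchanged", {
  sp <- randomAcquisition()
  expect_identical(applyNoise(sp, zeroNoise()), sp)
})

test_that("read-noise amplitude is recovered from a flat region", {
  # constant reflectance, read noise only: the SD of (noisy - clean) on the
  # flat spectrum should match the configured amplitude
  spec <- MotionSpec(0.5, displacement = 1, duration = 60)
  cfg <- smallCfg(64)
  clean <- simulateAcquisition(spec, card = whiteCard(), cfg = cfg,
                               noise = zeroNoise())
  noise <- NoiseModel(readNoiseSd = 10, shotNoiseScale = 0,
                      driftAmplitude = 0, seed = 11L)
  noisy <- applyNoise(clean, noise)
  resid <- intensities(noisy) - intensities(clean)
  flat <- wavelengthAxis(clean) < 620   # far from the line: no clamping
  resid <- resid[flat, ]
  expect_gt(length(resid), 1e4)
  expect_lt(abs(stats::sd(resid) - 10) / 10, 0.05)
})

test_that("noisy counts are clamped at the detector floor", {
  sp <- randomAcquisition()
  noisy <- applyNoise(sp, NoiseModel(readNoiseSd = 5000, shotNoiseScale = 0,
                                     driftAmplitude = 0, seed = 3L))
  expect_gte(min(intensities(noisy)), 0)
})

test_that("acquisition metadata records the run parameters", {
  spec <- MotionSpec(0.3291, displacement = 2, duration = 5, label = "demo")
  sp <- simulateAcquisition(spec, cfg = smallCfg(),
                            noise = NoiseModel(seed = 1L))
  md <- S4Vectors::metadata(sp)
  expect_equal(md$motion$frequency_hz, 0.3291)
  expect_equal(md$card$bar_center_offset_mm, -10)
  expect_equal(md$sample_rate, 10)
  expect_equal(md$noise$seed, 1L)
})
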