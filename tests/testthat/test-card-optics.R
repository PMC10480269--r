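test_that("reflectance field is black in bars, white on card, zero off-card", {
  card <- StripedCard()   # one 2 mm bar centred at 0
  expect_equal(reflectanceProfile(card, 0), 0.05)
  expect_equal(reflectanceProfile(card, 0.9), 0.05)
  expect_equal(reflectanceProfile(card, 10), 0.90)
  expect_equal(reflectanceProfile(card, c(-49, 49)), c(0.90, 0.90))
  expect_equal(reflectanceProfile(card, c(-51, 51, 200)), c(0, 0, 0))
})

test_that("spot fully on white card reflects the white fraction", {
  expect_equal(reflectedFraction(whiteCard(), LaserSpot(), 0), 0.90)
  expect_equal(reflectedFraction(whiteCard(), LaserSpot(profile = "gaussian"),
                                 0), 0.90, tolerance = 1e-9)
})

test_that("spot on a bar edge averages the two reflectances equally", {
  # 2 mm tophat spot centred on the edge of a 2 mm bar flanked by white:
  # half the footprint sees black, half white
  card <- StripedCard()
  expect_equal(reflectedFraction(card, LaserSpot(), 0.1), (0.90 + 0.05) / 2,
               tolerance = 1e-12)
})

test_that("concentric spot matches a fine 1D chord-weighted quadrature", {
  card <- StripedCard()
  spot <- LaserSpot()
  # oracle: 1 um midpoint quadrature of profile x chord weight over the disc
  r <- spot@diameter / 2
  u <- seq(-r + 5e-4, r - 5e-4, by = 1e-3)
  w <- 2 * sqrt(r^2 - u^2)
  oracle <- sum(w * reflectanceProfile(card, u)) / sum(w)
  expect_equal(reflectedFraction(card, spot, 0), oracle, tolerance = 1e-6)
})

test_that("overlap agrees with a rasterized 2D disc oracle", {
  withr::local_seed(101)
  card <- StripedCard(nDarkBars = 2, barCenterOffset = 3)
  spot <- LaserSpot()
  disp <- runif(100, -6, 6)   # mm travel across the stripe pattern
  got <- reflectedFraction(card, spot, disp)
  want <- vapply(disp, function(d) rasterOverlap(card, spot, d), numeric(1))
  expect_lt(max(abs(got - want)), 1e-3)
})

test_that("overlap is bounded, continuous and symmetric for a centred bar", {
  card <- StripedCard()
  spot <- LaserSpot()
  d <- seq(-4, 4, by = 0.01)  # cm; spot stays on the 100 mm card
  v <- reflectedFraction(card, spot, d)
  expect_true(all(v >= 0.05 - 1e-12 & v <= 0.90 + 1e-12))
  # symmetry about mid-travel when the bar is centred
  expect_equal(v, rev(v), tolerance = 1e-12)
  # continuity: no jumps larger than the local slope allows
  expect_lt(max(abs(diff(v))), 0.1)
})

test_that("gaussian profile also matches its quadrature oracle", {
  card <- StripedCard(barCenterOffset = 1.2)
  spot <- LaserSpot(profile = "gaussian")
  sigma <- spot@diameter / (2 * sqrt(2 * log(2)))
  u <- seq(-6 * sigma, 6 * sigma, by = 1e-4)
  w <- exp(-u^2 / (2 * sigma^2))
  for (d in c(-0.2, 0, 0.13)) {
    oracle <- sum(w * reflectanceProfile(card, 10 * d + u)) / sum(w)
    expect_equal(reflectedFraction(card, spot, d), oracle, tolerance = 1e-4)
  }
})

test_that("the default simulator card puts its bar at the travel turning point", {
  spec <- MotionSpec(0.3291, displacement = 2)
  card <- defaultCardFor(spec)
  expect_equal(card@barCenterOffset, -10)   # -travel/2 in mm
  # scaled by the geometry factor
  card2 <- defaultCardFor(spec, LaserSpot(geometryFactor = 0.5))
  expect_equal(card2@barCenterOffset, -5)
})

test_that("card parameters are validated", {
  expect_error(StripedCard(reflectanceBlack = 0.95), "reflectance")
  expect_error(StripedCard(barWidth = -1), "barWidth")
  expect_error(StripedCard(barCenterOffset = 60), "within cardExtent")
  expect_error(reflectedFraction(StripedCard(), LaserSpot(), Inf), "finite")
})
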