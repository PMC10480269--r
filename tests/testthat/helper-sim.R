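# Reduced spectrometer settings for fast unit tests: a narrow grid around the
# laser line. The full-resolution default grid is exercised in the
# acceptance-level tests.
smallCfg <- function(nPoints = 128, sampleRate = 10)
  SpectrometerConfig(wavelengthGrid = seq(600, 660, length.out = nPoints),
                     sampleRate = sampleRate)

# a card whose single bar is far from the spot travel (uniform white field)
whiteCard <- function() StripedCard(barCenterOffset = -45)

# brute-force 2D rasterized-disc oracle for the spot/card overlap: average
# card reflectance over 10 um pixels inside the disc. Each pixel's
# reflectance is averaged over sub-points across its width so the pixel
# grid, not the reflectance sampling, is the only discretization.
rasterOverlap <- function(card, spot, displacement, pitch = 0.01) {
  r <- spot@diameter / 2
  ax <- seq(-r + pitch / 2, r - pitch / 2, by = pitch)
  sub <- seq(-pitch / 2, pitch / 2, length.out = 7)[-c(1, 7)]
  x0 <- 10 * spot@geometryFactor * displacement
  rx <- rowMeans(vapply(sub, function(s)
    reflectanceProfile(card, x0 + ax + s), numeric(length(ax))))
  gridXY <- expand.grid(xi = seq_along(ax), y = ax)
  inside <- ax[gridXY$xi]^2 + gridXY$y^2 <= r^2
  mean(rx[gridXY$xi[inside]])
}

# small random acquisition for round-trip tests
randomAcquisition <- function(nWl = 16, nFrames = 20) {
  m <- matrix(stats::runif(nWl * nFrames, 0, 5000), nrow = nWl)
  TimeResolvedSpectra(m, wavelength = sort(stats::runif(nWl, 400, 900)),
                      time = (seq_len(nFrames) - 1) / 10,
                      metadata = list(tag = "random"))
}
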