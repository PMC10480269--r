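# Gaussian laser line shape on the wavelength grid, unit peak
lineShape <- function(cfg, spot) {
  g <- cfg@wavelengthGrid
  if (spot@centerWavelength < g[1] || spot@centerWavelength > g[length(g)])
    stop(sprintf("wavelength grid [%g, %g] nm does not cover the laser line at %g nm",
                 g[1], g[length(g)], spot@centerWavelength))
  exp(-4 * log(2) * ((g - spot@centerWavelength) / spot@linewidthFwhm)^2)
}

#' Render one spectrometer frame
#'
#' One spectrum (counts per wavelength): the dark baseline plus a Gaussian
#' line at the laser wavelength whose peak amplitude is
#' `integrationScale * reflected`.
#'
#' @param reflected reflected fraction in `[0, 1]`
#' @param cfg a \linkS4class{SpectrometerConfig}
#' @param spot a \linkS4class{LaserSpot}
#' @return numeric vector of counts, one per wavelength bin, strictly
#'   positive
#' @export
renderFrame <- function(reflected, cfg = SpectrometerConfig(),
                        spot = LaserSpot()) {
  stopifnot(length(reflected) == 1L, reflected >= 0, reflected <= 1)
  cfg@baseline + cfg@integrationScale * reflected * lineShape(cfg, spot)
}

#' Simulate a time-resolved acquisition
#'
#' The forward model end to end: sample the platform displacement, map each
#' sample to a reflected fraction through the card/spot overlap, render every
#' frame as a spectrum, and apply the noise model. With all noise amplitudes
#' zero the output is fully deterministic; with a seeded
#' \linkS4class{NoiseModel} it is bit-reproducible.
#'
#' @param spec a \linkS4class{MotionSpec}
#' @param card a \linkS4class{StripedCard}, or `NULL` to use
#'   [defaultCardFor()] (a bar at the lower turning point of the travel)
#' @param spot a \linkS4class{LaserSpot}
#' @param cfg a \linkS4class{SpectrometerConfig}; `cfg@sampleRate` must
#'   exceed twice `spec@frequency`
#' @param noise a \linkS4class{NoiseModel}; [zeroNoise()] for a noiseless run
#' @return a \linkS4class{TimeResolvedSpectra} with
#'   `floor(duration * sampleRate)` frames and acquisition parameters in its
#'   `metadata()`
#' @examples
#' sp <- simulateAcquisition(MotionSpec(0.3291, displacement = 2,
#'                                      duration = 10),
#'                           noise = zeroNoise())
#' dim(sp)
#' @export
simulateAcquisition <- function(spec, card = NULL, spot = LaserSpot(),
                                cfg = SpectrometerConfig(),
                                noise = NoiseModel()) {
  stopifnot(is(spec, "MotionSpec"), is(spot, "LaserSpot"),
            is(cfg, "SpectrometerConfig"), is(noise, "NoiseModel"))
  if (is.null(card)) card <- defaultCardFor(spec, spot)
  validObject(spec); validObject(card); validObject(cfg); validObject(noise)
  ds <- displacementSeries(spec, cfg@sampleRate)
  refl <- reflectedFraction(card, spot, ds$displacement_cm)
  m <- cfg@baseline +
    cfg@integrationScale * outer(lineShape(cfg, spot), refl)
  spectra <- TimeResolvedSpectra(
    m, wavelength = cfg@wavelengthGrid, time = ds$time_s,
    metadata = list(
      motion = list(frequency_hz = spec@frequency,
                    displacement_cm = spec@displacement,
                    waveform = spec@waveform, phase = spec@phase,
                    duration_s = spec@duration, label = spec@label),
      card = list(bar_width_mm = card@barWidth,
                  n_dark_bars = card@nDarkBars,
                  bar_center_offset_mm = card@barCenterOffset),
      spot = list(diameter_mm = spot@diameter, profile = spot@profile,
                  center_nm = spot@centerWavelength,
                  linewidth_fwhm_nm = spot@linewidthFwhm,
                  geometry_factor = spot@geometryFactor),
      sample_rate = cfg@sampleRate,
      baseline = cfg@baseline,
      integration_scale = cfg@integrationScale,
      noise = list(read_noise_sd = noise@readNoiseSd,
                   shot_noise_scale = noise@shotNoiseScale,
                   drift_amplitude = noise@driftAmplitude,
                   drift_period_s = noise@driftPeriod,
                   seed = noise@seed)))
  applyNoise(spectra, noise)
}

#' Apply the noise model to an acquisition
#'
#' Adds Gaussian read noise, signal-proportional Gaussian shot noise and a
#' slow sinusoidal baseline drift (common to all wavelengths of a frame,
#' random phase), then clamps at the detector floor of zero. With every
#' amplitude zero the input is returned unchanged. A non-`NA` seed makes the
#' draw reproducible and leaves the caller's RNG stream untouched.
#'
#' @param spectra a \linkS4class{TimeResolvedSpectra}
#' @param noise a \linkS4class{NoiseModel}
#' @return a \linkS4class{TimeResolvedSpectra}
#' @export
applyNoise <- function(spectra, noise) {
  stopifnot(is(spectra, "TimeResolvedSpectra"), is(noise, "NoiseModel"))
  if (noise@readNoiseSd == 0 && noise@shotNoiseScale == 0 &&
      noise@driftAmplitude == 0)
    return(spectra)
  draw <- function() {
    m <- intensities(spectra)
    n <- length(m)
    noisy <- m + stats::rnorm(n, sd = noise@readNoiseSd) +
      stats::rnorm(n) * noise@shotNoiseScale * m
    if (noise@driftAmplitude > 0) {
      tm <- timeAxis(spectra)
      phi <- stats::runif(1, 0, 2 * pi)
      drift <- noise@driftAmplitude *
        sin(2 * pi * tm / noise@driftPeriod + phi)
      noisy <- sweep(noisy, 2, drift, `+`)
    }
    pmax(noisy, 0)
  }
  noisy <- if (is.na(noise@seed)) draw() else
    withr::with_seed(noise@seed, draw())
  TimeResolvedSpectra(noisy, wavelength = wavelengthAxis(spectra),
                      time = timeAxis(spectra),
                      metadata = metadata(spectra))
}
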