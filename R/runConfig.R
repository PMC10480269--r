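#' Read and write a simulation run configuration
#'
#' A flat YAML file bundling every parameter of a simulated acquisition —
#' motion, card, spot, spectrometer and noise settings plus the seed — so a
#' run can be reproduced from one document. Omitted keys take the class
#' defaults; `writeRunConfig()` always writes the full set.
#'
#' @param path YAML file path
#' @return `readRunConfig()` returns a named list with elements `motion`
#'   (\linkS4class{MotionSpec}), `card` (\linkS4class{StripedCard} or `NULL`
#'   for the motion-dependent default), `spot` (\linkS4class{LaserSpot}),
#'   `cfg` (\linkS4class{SpectrometerConfig}) and `noise`
#'   (\linkS4class{NoiseModel}), ready to splice into
#'   [simulateAcquisition()].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  motion <- MotionSpec(
    frequency = pick("motion_frequency_hz", 0.25),
    displacement = pick("motion_displacement_cm", 2),
    waveform = pick("motion_waveform", "sine"),
    phase = pick("motion_phase_rad", 0),
    duration = pick("motion_duration_s", 60),
    label = pick("label", ""))
  card <- if (is.null(y$card_bar_center_offset_mm)) NULL else
    StripedCard(barWidth = pick("card_bar_width_mm", 2),
                nDarkBars = pick("card_n_dark_bars", 1),
                barCenterOffset = y$card_bar_center_offset_mm,
                reflectanceWhite = pick("card_reflectance_white", 0.90),
                reflectanceBlack = pick("card_reflectance_black", 0.05),
                cardExtent = pick("card_extent_mm", 100))
  spot <- LaserSpot(
    diameter = pick("spot_diameter_mm", 2),
    profile = pick("spot_profile", "tophat"),
    centerWavelength = pick("spot_center_wavelength_nm", 632.8),
    linewidthFwhm = pick("spot_linewidth_fwhm_nm", 1.5),
    power = pick("spot_power_mw", 3),
    geometryFactor = pick("spot_geometry_factor", 1))
  cfg <- SpectrometerConfig(
    wavelengthGrid = seq(pick("grid_min_nm", 345), pick("grid_max_nm", 1040),
                         length.out = pick("grid_n_points", 3648)),
    sampleRate = pick("sample_rate_hz", 10),
    integrationScale = pick("integration_scale", 10000),
    baseline = pick("baseline_counts", 150))
  noise <- NoiseModel(
    readNoiseSd = pick("noise_read_sd", 200),
    shotNoiseScale = pick("noise_shot_scale", 0.02),
    driftAmplitude = pick("noise_drift_amplitude", 500),
    driftPeriod = pick("noise_drift_period_s", 120),
    seed = pick("seed", NA_integer_))
  list(motion = motion, card = card, spot = spot, cfg = cfg, noise = noise)
}

#' @rdname readRunConfig
#' @param motion,card,spot,cfg,noise parameter objects; `card = NULL` writes
#'   no card keys (the motion-dependent default card is used on read)
#' @export
writeRunConfig <- function(path, motion, card = NULL, spot = LaserSpot(),
                           cfg = SpectrometerConfig(),
                           noise = NoiseModel()) {
  g <- cfg@wavelengthGrid
  y <- list(
    label = motion@label,
    motion_frequency_hz = motion@frequency,
    motion_displacement_cm = motion@displacement,
    motion_waveform = motion@waveform,
    motion_phase_rad = motion@phase,
    motion_duration_s = motion@duration,
    spot_diameter_mm = spot@diameter,
    spot_profile = spot@profile,
    spot_center_wavelength_nm = spot@centerWavelength,
    spot_linewidth_fwhm_nm = spot@linewidthFwhm,
    spot_power_mw = spot@power,
    spot_geometry_factor = spot@geometryFactor,
    grid_min_nm = g[1], grid_max_nm = g[length(g)],
    grid_n_points = length(g),
    sample_rate_hz = cfg@sampleRate,
    integration_scale = cfg@integrationScale,
    baseline_counts = cfg@baseline,
    noise_read_sd = noise@readNoiseSd,
    noise_shot_scale = noise@shotNoiseScale,
    noise_drift_amplitude = noise@driftAmplitude,
    noise_drift_period_s = noise@driftPeriod)
  if (!is.na(noise@seed)) y$seed <- noise@seed
  if (!is.null(card)) {
    y$card_bar_width_mm <- card@barWidth
    y$card_n_dark_bars <- card@nDarkBars
    y$card_bar_center_offset_mm <- card@barCenterOffset
    y$card_reflectance_white <- card@reflectanceWhite
    y$card_reflectance_black <- card@reflectanceBlack
    y$card_extent_mm <- card@cardExtent
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
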