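#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

scalarOk <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

## ---------------------------------------------------------------- MotionSpec

#' Platform / chest-wall motion specification
#'
#' Describes the periodic vertical motion being measured: its frequency `f`
#' (Hz), peak-to-peak displacement (cm), waveform shape, phase and duration.
#' The displacement amplitude of the underlying model
#' \eqn{b(t) = b_{max}\sin(2\pi f t + \phi)} is half the peak-to-peak
#' displacement: the stage travels between two stops spaced by the step.
#'
#' @slot frequency oscillation frequency, cycles per second (Hz)
#' @slot displacement peak-to-peak vertical travel, cm
#' @slot waveform `"sine"` (the ideal model) or `"triangle"`
#'   (constant-speed travel, what a constant-RPM stepper actually produces)
#' @slot phase phase offset in radians, in `[0, 2*pi)`
#' @slot duration record length in seconds
#' @slot label free-text description
#'
#' @param frequency,displacement,waveform,phase,duration,label see slots
#' @return `MotionSpec()` returns a validated `MotionSpec` object.
#' @examples
#' MotionSpec(frequency = 0.3291, displacement = 2)
#' @export
setClass("MotionSpec",
  representation(frequency = "numeric", displacement = "numeric",
                 waveform = "character", phase = "numeric",
                 duration = "numeric", label = "character"),
  prototype(frequency = 0.25, displacement = 2, waveform = "sine",
            phase = 0, duration = 60, label = ""))

setValidity("MotionSpec", function(object) {
  msg <- character()
  if (!scalarOk(object@frequency) || object@frequency <= 0)
    msg <- c(msg, "frequency must be a positive scalar (Hz)")
  if (!scalarOk(object@displacement) || object@displacement <= 0)
    msg <- c(msg, "displacement must be a positive scalar (cm)")
  if (!scalarOk(object@duration) || object@duration <= 0)
    msg <- c(msg, "duration must be a positive scalar (s)")
  if (!scalarOk(object@phase) || object@phase < 0 || object@phase >= 2 * pi)
    msg <- c(msg, "phase must lie in [0, 2*pi)")
  if (!object@waveform %in% c("sine", "triangle"))
    msg <- c(msg, "waveform must be 'sine' or 'triangle'")
  if (length(msg)) msg else TRUE
})

#' @rdname MotionSpec-class
#' @export
MotionSpec <- function(frequency, displacement = 2, waveform = "sine",
                       phase = 0, duration = 60, label = "") {
  new("MotionSpec", frequency = as.numeric(frequency),
      displacement = as.numeric(displacement), waveform = waveform,
      phase = as.numeric(phase), duration = as.numeric(duration),
      label = label)
}

## --------------------------------------------------------------- StripedCard

#' Striped reflectance card
#'
#' One-dimensional reflectance field of the black/white striped card along the
#' travel axis, in mm, centred on the card midpoint. Dark bars of width
#' `barWidth` sit at `barCenterOffset` (a single bar) or, for
#' `nDarkBars > 1`, form an alternating stripe pattern with period
#' `2 * barWidth` centred there. Off-card positions reflect nothing.
#'
#' The stripes are long compared with the laser spot, so the transverse
#' dimension integrates out and a 1D field suffices; the circular spot becomes
#' a chord-weighted 1D kernel (see [reflectedFraction()]).
#'
#' @slot barWidth dark-bar width, mm
#' @slot nDarkBars number of dark bars
#' @slot barCenterOffset centre of the bar pattern, mm from the card midpoint
#' @slot reflectanceWhite,reflectanceBlack diffuse reflectance fractions of
#'   the white card and the dark bars
#' @slot cardExtent full card length along the travel axis, mm
#' @param barWidth,nDarkBars,barCenterOffset,reflectanceWhite,reflectanceBlack,cardExtent
#'   see slots
#' @examples
#' reflectanceProfile(StripedCard(), c(-10, 0, 10, 80))
#' @export
setClass("StripedCard",
  representation(barWidth = "numeric", nDarkBars = "numeric",
                 barCenterOffset = "numeric", reflectanceWhite = "numeric",
                 reflectanceBlack = "numeric", cardExtent = "numeric"),
  prototype(barWidth = 2, nDarkBars = 1, barCenterOffset = 0,
            reflectanceWhite = 0.90, reflectanceBlack = 0.05,
            cardExtent = 100))

setValidity("StripedCard", function(object) {
  msg <- character()
  if (!scalarOk(object@barWidth) || object@barWidth <= 0)
    msg <- c(msg, "barWidth must be positive (mm)")
  if (!scalarOk(object@nDarkBars) || object@nDarkBars < 1 ||
      object@nDarkBars != round(object@nDarkBars))
    msg <- c(msg, "nDarkBars must be a positive integer")
  if (!(object@reflectanceBlack >= 0 &&
        object@reflectanceBlack < object@reflectanceWhite &&
        object@reflectanceWhite <= 1))
    msg <- c(msg, "need 0 <= reflectanceBlack < reflectanceWhite <= 1")
  ctr <- barCenters(object)
  if (length(ctr) &&
      max(abs(ctr)) + object@barWidth / 2 > object@cardExtent / 2 + 1e-9)
    msg <- c(msg, "all dark bars must lie within cardExtent")
  if (length(msg)) msg else TRUE
})

#' @rdname StripedCard-class
#' @export
StripedCard <- function(barWidth = 2, nDarkBars = 1, barCenterOffset = 0,
                        reflectanceWhite = 0.90, reflectanceBlack = 0.05,
                        cardExtent = 100) {
  new("StripedCard", barWidth = barWidth, nDarkBars = nDarkBars,
      barCenterOffset = barCenterOffset,
      reflectanceWhite = reflectanceWhite,
      reflectanceBlack = reflectanceBlack, cardExtent = cardExtent)
}

# bar centre positions (mm); alternating pattern with period 2*barWidth
barCenters <- function(card) {
  n <- card@nDarkBars
  card@barCenterOffset + (seq_len(n) - (n + 1) / 2) * 2 * card@barWidth
}

## ----------------------------------------------------------------- LaserSpot

#' Laser illumination spot
#'
#' The He-Ne style illumination footprint on the card: a 2 mm spot at
#' 632.8 nm by default. `geometryFactor` scales card-relative spot travel per
#' unit platform travel; it absorbs the projection geometry of the tilted
#' source (a small tilt keeps the reflection inside the collection cone but
#' barely changes the travel mapping, hence default 1).
#'
#' @slot diameter spot diameter on the card, mm (FWHM for the gaussian
#'   profile)
#' @slot profile `"tophat"` (uniform disc) or `"gaussian"`
#' @slot centerWavelength laser line centre, nm
#' @slot linewidthFwhm instrument-broadened line width (FWHM), nm
#' @slot power optical power, mW (carried as metadata; intensities are in
#'   arbitrary counts)
#' @slot geometryFactor card-relative spot travel per unit platform travel
#' @param diameter,profile,centerWavelength,linewidthFwhm,power,geometryFactor
#'   see slots
#' @export
setClass("LaserSpot",
  representation(diameter = "numeric", profile = "character",
                 centerWavelength = "numeric", linewidthFwhm = "numeric",
                 power = "numeric", geometryFactor = "numeric"),
  prototype(diameter = 2, profile = "tophat", centerWavelength = 632.8,
            linewidthFwhm = 1.5, power = 3, geometryFactor = 1))

setValidity("LaserSpot", function(object) {
  msg <- character()
  if (!scalarOk(object@diameter) || object@diameter <= 0)
    msg <- c(msg, "diameter must be positive (mm)")
  if (!object@profile %in% c("tophat", "gaussian"))
    msg <- c(msg, "profile must be 'tophat' or 'gaussian'")
  if (!scalarOk(object@centerWavelength) || object@centerWavelength <= 0)
    msg <- c(msg, "centerWavelength must be positive (nm)")
  if (!scalarOk(object@geometryFactor) || object@geometryFactor <= 0 ||
      object@geometryFactor > 2)
    msg <- c(msg, "geometryFactor must lie in (0, 2]")
  if (!scalarOk(object@linewidthFwhm) || object@linewidthFwhm <= 0)
    msg <- c(msg, "linewidthFwhm must be positive (nm)")
  if (length(msg)) msg else TRUE
})

#' @rdname LaserSpot-class
#' @export
LaserSpot <- function(diameter = 2, profile = "tophat",
                      centerWavelength = 632.8, linewidthFwhm = 1.5,
                      power = 3, geometryFactor = 1) {
  new("LaserSpot", diameter = diameter, profile = profile,
      centerWavelength = centerWavelength, linewidthFwhm = linewidthFwhm,
      power = power, geometryFactor = geometryFactor)
}

## ------------------------------------------------------- SpectrometerConfig

#' Spectrometer acquisition configuration
#'
#' Wavelength grid and frame-rate settings of the (simulated) fibre
#' spectrometer. Defaults mirror a compact CCD instrument: 3648 pixels
#' spanning 345-1040 nm, read out at 10 frames per second.
#'
#' @slot wavelengthGrid strictly increasing wavelength axis, nm; must cover
#'   the laser line
#' @slot sampleRate frame rate, frames per second (Hz)
#' @slot integrationScale detector counts per unit reflected fraction at the
#'   line peak
#' @slot baseline dark baseline, counts
#' @param wavelengthGrid,sampleRate,integrationScale,baseline see slots
#' @export
setClass("SpectrometerConfig",
  representation(wavelengthGrid = "numeric", sampleRate = "numeric",
                 integrationScale = "numeric", baseline = "numeric"),
  prototype(wavelengthGrid = seq(345, 1040, length.out = 3648),
            sampleRate = 10, integrationScale = 10000, baseline = 150))

setValidity("SpectrometerConfig", function(object) {
  msg <- character()
  g <- object@wavelengthGrid
  if (length(g) < 2L || any(diff(g) <= 0))
    msg <- c(msg, "wavelengthGrid must be strictly increasing")
  if (!scalarOk(object@sampleRate) || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be positive (Hz)")
  if (!scalarOk(object@baseline) || object@baseline < 0)
    msg <- c(msg, "baseline must be non-negative (counts)")
  if (!scalarOk(object@integrationScale) || object@integrationScale <= 0)
    msg <- c(msg, "integrationScale must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SpectrometerConfig-class
#' @export
SpectrometerConfig <- function(wavelengthGrid = seq(345, 1040,
                                                    length.out = 3648),
                               sampleRate = 10, integrationScale = 10000,
                               baseline = 150) {
  new("SpectrometerConfig", wavelengthGrid = as.numeric(wavelengthGrid),
      sampleRate = sampleRate, integrationScale = integrationScale,
      baseline = baseline)
}

## ---------------------------------------------------------------- NoiseModel

#' Detector and environment noise model
#'
#' Additive Gaussian read noise, signal-proportional Gaussian shot noise and a
#' slow sinusoidal baseline drift; noisy counts are clamped at the physical
#' detector floor of zero. The defaults are the package's calibrated preset:
#' read noise 2% of the line peak (200 counts at the default
#' `integrationScale`), shot-noise scale 0.02, drift 5% of peak with a 120 s
#' period. `seed = NA` leaves the caller's RNG stream untouched; an integer
#' seed makes the acquisition bit-reproducible without disturbing the global
#' RNG state.
#'
#' @slot readNoiseSd additive read-noise SD, counts
#' @slot shotNoiseScale SD of the signal-proportional component, as a
#'   fraction of the signal
#' @slot driftAmplitude baseline drift amplitude, counts
#' @slot driftPeriod baseline drift period, seconds
#' @slot seed integer RNG seed, or `NA`
#' @param readNoiseSd,shotNoiseScale,driftAmplitude,driftPeriod,seed see slots
#' @seealso [zeroNoise()] for the noiseless model
#' @export
setClass("NoiseModel",
  representation(readNoiseSd = "numeric", shotNoiseScale = "numeric",
                 driftAmplitude = "numeric", driftPeriod = "numeric",
                 seed = "integer"),
  prototype(readNoiseSd = 200, shotNoiseScale = 0.02, driftAmplitude = 500,
            driftPeriod = 120, seed = NA_integer_))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@readNoiseSd < 0 || object@shotNoiseScale < 0 ||
      object@driftAmplitude < 0)
    msg <- c(msg, "noise amplitudes must be non-negative")
  if (object@driftAmplitude > 0 &&
      (!scalarOk(object@driftPeriod) || object@driftPeriod <= 0))
    msg <- c(msg, "driftPeriod must be positive when driftAmplitude > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname NoiseModel-class
#' @export
NoiseModel <- function(readNoiseSd = 200, shotNoiseScale = 0.02,
                       driftAmplitude = 500, driftPeriod = 120,
                       seed = NA_integer_) {
  new("NoiseModel", readNoiseSd = readNoiseSd,
      shotNoiseScale = shotNoiseScale, driftAmplitude = driftAmplitude,
      driftPeriod = driftPeriod, seed = as.integer(seed))
}

#' @rdname NoiseModel-class
#' @param seed optional RNG seed (irrelevant when all amplitudes are zero)
#' @export
zeroNoise <- function(seed = NA_integer_) {
  NoiseModel(readNoiseSd = 0, shotNoiseScale = 0, driftAmplitude = 0,
             driftPeriod = 120, seed = seed)
}

## ------------------------------------------------------- TimeResolvedSpectra

#' Time-resolved spectra container
#'
#' The central data structure: a stack of spectrometer frames stored as a
#' \linkS4class{SummarizedExperiment} with wavelengths as rows and frames as
#' columns. `rowData` carries `wavelength_nm`, `colData` carries `time_s`
#' (strictly increasing and uniform), and `metadata()` the acquisition
#' parameters. This is the "intensity-wavelength-time matrix" from which the
#' respiration waveform is sliced.
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}
#' @param intensities numeric matrix, wavelengths x frames, counts (>= 0)
#' @param wavelength wavelength axis, nm, strictly increasing
#' @param time frame time axis, seconds, uniform
#' @param metadata list of acquisition parameters
#' @return a `TimeResolvedSpectra` object
#' @seealso [simulateAcquisition()], [extractWaveform()], [readCube()]
#' @examples
#' m <- matrix(rep(150, 12), nrow = 4)
#' TimeResolvedSpectra(m, wavelength = c(630, 631, 632, 633),
#'                     time = c(0, 0.1, 0.2))
#' @export
setClass("TimeResolvedSpectra", contains = "SummarizedExperiment")

setValidity("TimeResolvedSpectra", function(object) {
  msg <- character()
  wl <- rowData(object)$wavelength_nm
  tm <- colData(object)$time_s
  if (is.null(wl) || any(diff(wl) <= 0))
    msg <- c(msg, "rowData$wavelength_nm must be strictly increasing")
  if (is.null(tm)) {
    msg <- c(msg, "colData$time_s is required")
  } else if (length(tm) > 1L) {
    dt <- diff(tm)
    if (any(dt <= 0))
      msg <- c(msg, "time axis must be strictly increasing")
    else if (max(dt) - min(dt) > 1e-9)
      msg <- c(msg, "time axis must be uniform to within 1e-9 s")
  }
  if (length(SummarizedExperiment::assays(object)) &&
      min(assay(object)) < 0)
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname TimeResolvedSpectra-class
#' @export
TimeResolvedSpectra <- function(intensities, wavelength, time,
                                metadata = list()) {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == length(wavelength),
            ncol(intensities) == length(time))
  se <- SummarizedExperiment(
    assays = list(counts = unname(intensities)),
    rowData = DataFrame(wavelength_nm = as.numeric(wavelength)),
    colData = DataFrame(time_s = as.numeric(time)))
  metadata(se) <- metadata
  new("TimeResolvedSpectra", se)
}

#' @rdname accessors
setMethod("intensities", "TimeResolvedSpectra",
          function(x) assay(x, "counts"))

#' @rdname accessors
setMethod("timeAxis", "TimeResolvedSpectra",
          function(x) colData(x)$time_s)

#' @rdname accessors
setMethod("wavelengthAxis", "TimeResolvedSpectra",
          function(x) rowData(x)$wavelength_nm)

#' @rdname TimeResolvedSpectra-class
#' @param x a `TimeResolvedSpectra`
#' @export
acquisitionRate <- function(x) {
  tm <- timeAxis(x)
  if (length(tm) < 2L) {
    r <- metadata(x)$sample_rate
    if (is.null(r)) NA_real_ else r
  } else 1 / mean(diff(tm))
}

## ------------------------------------------------------- RespirationWaveform

#' Extracted respiration waveform
#'
#' Intensity-time section at the laser line: one value per frame on a uniform
#' time axis, plus a provenance list recording how it was extracted and what
#' processing has been applied.
#'
#' @slot values intensity values (counts, or detrended counts)
#' @slot time time axis, seconds
#' @slot provenance list of extraction / processing parameters
#' @param values,time,provenance see slots
#' @export
setClass("RespirationWaveform",
  representation(values = "numeric", time = "numeric", provenance = "list"),
  prototype(values = numeric(), time = numeric(), provenance = list()))

setValidity("RespirationWaveform", function(object) {
  msg <- character()
  if (length(object@values) != length(object@time))
    msg <- c(msg, "values and time must have equal length")
  if (length(object@time) > 1L) {
    dt <- diff(object@time)
    if (any(dt <= 0) || max(dt) - min(dt) > 1e-9)
      msg <- c(msg, "time axis must be uniform and increasing")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname RespirationWaveform-class
#' @export
RespirationWaveform <- function(values, time, provenance = list()) {
  new("RespirationWaveform", values = as.numeric(values),
      time = as.numeric(time), provenance = provenance)
}

#' @rdname accessors
setMethod("intensities", "RespirationWaveform", function(x) x@values)

#' @rdname accessors
setMethod("timeAxis", "RespirationWaveform", function(x) x@time)

#' @rdname accessors
setMethod("provenance", "RespirationWaveform", function(x) x@provenance)

## --------------------------------------------------------- FrequencySpectrum

#' One-sided magnitude spectrum
#'
#' DFT magnitude spectrum of a respiration waveform on the non-negative
#' frequency half-axis. `binResolution` is the frequency spacing,
#' `sample_rate / (n * zeroPadFactor)`; `nTime`/`nPadded` record the original
#' and zero-padded lengths so energy identities can be checked against the
#' time series.
#'
#' @slot frequency frequency axis, Hz, ascending from 0
#' @slot magnitude DFT modulus at each frequency, non-negative
#' @slot resolution bin width, Hz
#' @slot nTime original number of time samples
#' @slot nPadded transform length after zero padding
#' @slot provenance list of transform parameters
#' @param frequency,magnitude,resolution,nTime,nPadded,provenance see slots
#' @export
setClass("FrequencySpectrum",
  representation(frequency = "numeric", magnitude = "numeric",
                 resolution = "numeric", nTime = "integer",
                 nPadded = "integer", provenance = "list"),
  prototype(frequency = numeric(), magnitude = numeric(), resolution = NA_real_,
            nTime = 0L, nPadded = 0L, provenance = list()))

setValidity("FrequencySpectrum", function(object) {
  msg <- character()
  if (length(object@frequency) != length(object@magnitude))
    msg <- c(msg, "frequency and magnitude must have equal length")
  if (length(object@frequency) &&
      (object@frequency[1] < 0 || any(diff(object@frequency) <= 0)))
    msg <- c(msg, "frequency axis must be non-negative and ascending")
  if (length(object@magnitude) && min(object@magnitude) < 0)
    msg <- c(msg, "magnitudes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname FrequencySpectrum-class
#' @export
FrequencySpectrum <- function(frequency, magnitude, resolution,
                              nTime, nPadded, provenance = list()) {
  new("FrequencySpectrum", frequency = frequency, magnitude = magnitude,
      resolution = resolution, nTime = as.integer(nTime),
      nPadded = as.integer(nPadded), provenance = provenance)
}

#' @rdname accessors
setMethod("frequencyAxis", "FrequencySpectrum", function(x) x@frequency)

#' @rdname accessors
setMethod("magnitudes", "FrequencySpectrum", function(x) x@magnitude)

#' @rdname accessors
setMethod("binResolution", "FrequencySpectrum", function(x) x@resolution)

#' @rdname accessors
setMethod("provenance", "FrequencySpectrum", function(x) x@provenance)

## --------------------------------------------------------- FrequencyEstimate

#' Dominant-frequency estimate
#'
#' The recovered oscillation frequency: location of the largest spectral
#' magnitude inside the searched band, optionally refined by three-point
#' parabolic interpolation. `bpm` is exactly `60 * frequency`.
#'
#' @slot frequency estimated frequency, Hz
#' @slot bpm estimated rate, breaths per minute
#' @slot peakMagnitude spectral magnitude at the peak
#' @slot binResolution underlying bin width, Hz
#' @slot band searched frequency band, Hz (length 2)
#' @slot provenance list of pipeline parameters
#' @param frequency,peakMagnitude,binResolution,band,provenance see slots
#' @export
setClass("FrequencyEstimate",
  representation(frequency = "numeric", bpm = "numeric",
                 peakMagnitude = "numeric", binResolution = "numeric",
                 band = "numeric", provenance = "list"))

setValidity("FrequencyEstimate", function(object) {
  msg <- character()
  if (!identical(object@bpm, 60 * object@frequency))
    msg <- c(msg, "bpm must equal 60 * frequency exactly")
  if (length(object@band) != 2L)
    msg <- c(msg, "band must have length 2")
  else if (object@frequency < object@band[1] ||
           object@frequency > object@band[2])
    msg <- c(msg, "frequency must lie inside the searched band")
  if (length(msg)) msg else TRUE
})

#' @rdname FrequencyEstimate-class
#' @export
FrequencyEstimate <- function(frequency, peakMagnitude, binResolution,
                              band, provenance = list()) {
  new("FrequencyEstimate", frequency = frequency, bpm = 60 * frequency,
      peakMagnitude = peakMagnitude, binResolution = binResolution,
      band = band, provenance = provenance)
}

#' @rdname accessors
setMethod("estimatedHz", "FrequencyEstimate", function(x) x@frequency)

#' @rdname accessors
setMethod("estimatedBpm", "FrequencyEstimate", function(x) x@bpm)

#' @rdname accessors
setMethod("binResolution", "FrequencyEstimate", function(x) x@binResolution)

#' @rdname accessors
setMethod("provenance", "FrequencyEstimate", function(x) x@provenance)

## ----------------------------------------------------------- ConfusionMetrics

#' Diagnostic classification summary
#'
#' Confusion counts and derived fractions for normal/abnormal respiratory-rate
#' classification. The abnormal (clinically alarmed) rate is the positive
#' class. Constructed by [confusionMetrics()].
#'
#' @slot tp,fp,tn,fn confusion counts
#' @slot sensitivity tp / (tp + fn), or `NA` when undefined
#' @slot specificity tn / (tn + fp), or `NA`
#' @slot positivePredictivity tp / (tp + fp), or `NA`
#' @slot accuracy (tp + tn) / n
#' @export
setClass("ConfusionMetrics",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer", sensitivity = "numeric",
                 specificity = "numeric", positivePredictivity = "numeric",
                 accuracy = "numeric"))

setValidity("ConfusionMetrics", function(object) {
  msg <- character()
  cnt <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  frac <- c(object@sensitivity, object@specificity,
            object@positivePredictivity, object@accuracy)
  bad <- !is.na(frac) & (frac < 0 | frac > 1)
  if (any(bad)) msg <- c(msg, "metric fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname confusion-accessors
setMethod("confusionCounts", "ConfusionMetrics", function(x)
  c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn))

#' @rdname confusion-accessors
setMethod("sensitivity", "ConfusionMetrics", function(x) x@sensitivity)

#' @rdname confusion-accessors
setMethod("specificity", "ConfusionMetrics", function(x) x@specificity)

#' @rdname confusion-accessors
setMethod("positivePredictivity", "ConfusionMetrics",
          function(x) x@positivePredictivity)

#' @rdname confusion-accessors
setMethod("accuracy", "ConfusionMetrics", function(x) x@accuracy)

## ------------------------------------------------------------------ GridReport

#' Grid-experiment report
#'
#' Result of [runGrid()]: one row per simulated recording (condition x
#' repeat) with the recovered frequency, percent absolute uncertainty and
#' normal/abnormal labels; a per-displacement mean +/- SD uncertainty
#' summary; the overall mean uncertainty; and the confusion metrics of the
#' classification.
#'
#' @slot results per-recording `data.frame`
#' @slot perDisplacement per-displacement summary `data.frame`
#' @slot overall overall mean percent uncertainty
#' @slot confusion a \linkS4class{ConfusionMetrics}
#' @slot parameters list of run parameters
#' @seealso [runGrid()], [writeGridReport()]
#' @export
setClass("GridReport",
  representation(results = "data.frame", perDisplacement = "data.frame",
                 overall = "numeric", confusion = "ConfusionMetrics",
                 parameters = "list"))

setValidity("GridReport", function(object) {
  msg <- character()
  need <- c("rpm", "step_cm", "repeat_idx", "true_hz", "estimated_hz",
            "uncertainty_pct", "true_class", "predicted_class")
  if (!all(need %in% names(object@results)))
    msg <- c(msg, paste("results must have columns:",
                        paste(need, collapse = ", ")))
  else if (nrow(object@results) &&
           abs(object@overall - mean(object@results$uncertainty_pct)) >
             1e-9 * max(1, object@overall))
    msg <- c(msg, "overall must equal the mean of all uncertainties")
  if (length(msg)) msg else TRUE
})

#' @rdname gridreport-accessors
setMethod("gridResults", "GridReport", function(x) x@results)

#' @rdname gridreport-accessors
setMethod("displacementSummary", "GridReport", function(x) x@perDisplacement)

#' @rdname gridreport-accessors
setMethod("overallUncertainty", "GridReport", function(x) x@overall)

#' @rdname gridreport-accessors
setMethod("gridConfusion", "GridReport", function(x) x@confusion)
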