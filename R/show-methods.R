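setMethod("show", "MotionSpec", function(object) {
  cat(sprintf("MotionSpec: %s, f = %g Hz (%g bpm), %g cm peak-to-peak,\n",
              object@waveform, object@frequency, 60 * object@frequency,
              object@displacement),
      sprintf("  phase %g rad, duration %g s%s\n", object@phase,
              object@duration,
              if (nzchar(object@label)) paste0(" [", object@label, "]")
              else ""))
})

setMethod("show", "StripedCard", function(object) {
  cat(sprintf(
    "StripedCard: %d dark bar(s) of %g mm at %+g mm, R = %.2f/%.2f, %g mm card\n",
    as.integer(object@nDarkBars), object@barWidth, object@barCenterOffset,
    object@reflectanceWhite, object@reflectanceBlack, object@cardExtent))
})

setMethod("show", "LaserSpot", function(object) {
  cat(sprintf(
    "LaserSpot: %g mm %s spot, line %g nm (FWHM %g nm), %g mW, geometry %g\n",
    object@diameter, object@profile, object@centerWavelength,
    object@linewidthFwhm, object@power, object@geometryFactor))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    "NoiseModel: read SD %g, shot scale %g, drift %g counts / %g s, seed %s\n",
    object@readNoiseSd, object@shotNoiseScale, object@driftAmplitude,
    object@driftPeriod,
    if (is.na(object@seed)) "NA" else as.character(object@seed)))
})

setMethod("show", "TimeResolvedSpectra", function(object) {
  tm <- timeAxis(object)
  wl <- wavelengthAxis(object)
  cat(sprintf("TimeResolvedSpectra: %d frames x %d wavelengths\n",
              ncol(object), nrow(object)))
  if (length(tm) > 1)
    cat(sprintf("  time %g-%g s at %.4g Hz; wavelengths %g-%g nm\n",
                tm[1], tm[length(tm)], acquisitionRate(object),
                wl[1], wl[length(wl)]))
  f <- metadata(object)$motion$frequency_hz
  if (!is.null(f)) cat(sprintf("  simulated motion at %g Hz\n", f))
})

setMethod("show", "RespirationWaveform", function(object) {
  cat(sprintf("RespirationWaveform: %d samples", length(object@values)))
  if (length(object@time) > 1)
    cat(sprintf(", %g-%g s", object@time[1],
                object@time[length(object@time)]))
  cat("\n")
})

setMethod("show", "FrequencySpectrum", function(object) {
  cat(sprintf(
    "FrequencySpectrum: %d bins, 0-%.4g Hz, resolution %.4g Hz (n = %d, padded %d)\n",
    length(object@frequency), max(object@frequency), object@resolution,
    object@nTime, object@nPadded))
})

setMethod("show", "FrequencyEstimate", function(object) {
  cat(sprintf(
    "FrequencyEstimate: %.4f Hz (%.2f bpm), bin %.4g Hz, band [%g, %g] Hz\n",
    object@frequency, object@bpm, object@binResolution,
    object@band[1], object@band[2]))
})

setMethod("show", "ConfusionMetrics", function(object) {
  fmt <- function(x) if (is.na(x)) "NA" else sprintf("%.3f", x)
  cat(sprintf("ConfusionMetrics (abnormal = positive): tp %d fp %d tn %d fn %d\n",
              object@tp, object@fp, object@tn, object@fn),
      sprintf("  sensitivity %s, specificity %s, positive predictivity %s, accuracy %s\n",
              fmt(object@sensitivity), fmt(object@specificity),
              fmt(object@positivePredictivity), fmt(object@accuracy)))
})

setMethod("show", "GridReport", function(object) {
  cat(sprintf("GridReport: %d recordings (%d conditions x %d repeats)\n",
              nrow(object@results),
              length(unique(paste(object@results$rpm,
                                  object@results$step_cm))),
              object@parameters$repeats))
  cat(sprintf("  overall mean absolute uncertainty: %.3f%%\n",
              object@overall))
  pd <- object@perDisplacement
  for (i in seq_len(nrow(pd)))
    cat(sprintf("  step %g cm: %.3f +/- %.3f %%\n", pd$step_cm[i],
                pd$mean_uncertainty_pct[i], pd$sd_uncertainty_pct[i]))
  show(object@confusion)
})
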