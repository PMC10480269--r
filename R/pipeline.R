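#' Slice the intensity-time section at the laser line
#'
#' Per-frame mean intensity over the wavelength bins within
#' `[center - bandHalfwidth, center + bandHalfwidth]` — the intensity-time
#' section at the laser wavelength from which the respiration waveform is
#' reconstructed.
#'
#' @param spectra a \linkS4class{TimeResolvedSpectra}
#' @param center slice centre, nm
#' @param bandHalfwidth half-width of the averaged band, nm
#' @return a \linkS4class{RespirationWaveform} with one value per frame
#' @export
extractWaveform <- function(spectra, center = 632, bandHalfwidth = 2) {
  stopifnot(is(spectra, "TimeResolvedSpectra"))
  wl <- wavelengthAxis(spectra)
  sel <- wl >= center - bandHalfwidth & wl <= center + bandHalfwidth
  if (!any(sel))
    stop(sprintf("no wavelength bins in [%g, %g] nm",
                 center - bandHalfwidth, center + bandHalfwidth))
  vals <- colMeans(intensities(spectra)[sel, , drop = FALSE])
  RespirationWaveform(vals, timeAxis(spectra),
                      provenance = list(center_nm = center,
                                        band_halfwidth_nm = bandHalfwidth,
                                        n_bins = sum(sel)))
}

#' Moving-average smoothing
#'
#' Centred moving average removing high-frequency distortions before the
#' transform. At the boundaries the window shrinks symmetrically instead of
#' padding with phantom zeros, so short records are not biased toward zero;
#' length is preserved and a constant signal passes through unchanged.
#'
#' @param wave a \linkS4class{RespirationWaveform}
#' @param window window length in samples; odd, between 1 and the record
#'   length. `window = 1` is the identity.
#' @return a smoothed \linkS4class{RespirationWaveform}
#' @export
movingAverage <- function(wave, window = 3) {
  stopifnot(is(wave, "RespirationWaveform"))
  n <- length(wave@values)
  if (window %% 2 != 1 || window < 1 || window > n)
    stop(sprintf("window must be odd and within [1, %d], got %g", n, window))
  if (window == 1) return(wave)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, wave@values))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  out <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  RespirationWaveform(out, wave@time,
                      provenance = c(wave@provenance,
                                     list(moving_average_window = window)))
}

#' Remove the linear trend
#'
#' Subtracts the least-squares linear fit against time, suppressing the DC
#' level and slow baseline drift so they cannot mask the physiological peak
#' in the spectrum.
#'
#' @param wave a \linkS4class{RespirationWaveform} of length >= 2
#' @return a zero-mean \linkS4class{RespirationWaveform}
#' @export
detrendWaveform <- function(wave) {
  stopifnot(is(wave, "RespirationWaveform"))
  n <- length(wave@values)
  if (n < 2) stop("detrending needs at least 2 samples")
  fit <- stats::lm.fit(cbind(1, wave@time), wave@values)
  RespirationWaveform(unname(fit$residuals), wave@time,
                      provenance = c(wave@provenance,
                                     list(detrended = TRUE)))
}

#' One-sided DFT magnitude spectrum
#'
#' Magnitude of the discrete Fourier transform of the waveform on the
#' non-negative frequency half-axis, optionally zero-padded for a finer bin
#' grid. The bin width is `sample_rate / (n * zeroPadFactor)`. Parseval's
#' identity between the time series and the full (two-sided) transform is
#' preserved; zero padding does not change signal energy.
#'
#' @param wave a \linkS4class{RespirationWaveform} on a uniform time axis
#' @param zeroPadFactor integer >= 1; transform length is
#'   `zeroPadFactor * length(wave)`
#' @return a \linkS4class{FrequencySpectrum}
#' @export
dftSpectrum <- function(wave, zeroPadFactor = 4) {
  stopifnot(is(wave, "RespirationWaveform"))
  validObject(wave)   # enforces the uniform time axis
  n <- length(wave@values)
  if (n < 2) stop("spectrum needs at least 2 samples")
  stopifnot(zeroPadFactor >= 1, zeroPadFactor == round(zeroPadFactor))
  dt <- mean(diff(wave@time))
  np <- as.integer(n * zeroPadFactor)
  x <- c(wave@values, rep(0, np - n))
  mag <- Mod(stats::fft(x))[seq_len(np %/% 2 + 1L)]
  res <- 1 / (np * dt)
  FrequencySpectrum(frequency = (seq_len(np %/% 2 + 1L) - 1L) * res,
                    magnitude = mag, resolution = res,
                    nTime = n, nPadded = np,
                    provenance = c(wave@provenance,
                                   list(zero_pad_factor = zeroPadFactor,
                                        sample_rate_hz = 1 / dt)))
}

#' Pick the dominant frequency in a band
#'
#' Frequency of the largest magnitude within the closed search band
#' (default 0.05-2.5 Hz, covering physiological respiratory rates with
#' margin while excluding DC). With `interpolate = TRUE` the peak location
#' is refined by a three-point parabolic fit through the peak bin and its
#' neighbours, giving sub-bin resolution. Exact ties break toward the lower
#' frequency.
#'
#' @param spectrum a \linkS4class{FrequencySpectrum}
#' @param band closed frequency interval to search, Hz; the lower edge must
#'   be positive (DC excluded)
#' @param interpolate refine the peak with parabolic interpolation?
#' @return a \linkS4class{FrequencyEstimate}
#' @export
pickFrequency <- function(spectrum, band = c(0.05, 2.5),
                          interpolate = TRUE) {
  stopifnot(is(spectrum, "FrequencySpectrum"))
  if (length(band) != 2L || band[1] >= band[2])
    stop("band must be an increasing interval c(lo, hi)")
  if (band[1] <= 0)
    stop("the search band must exclude DC (band[1] > 0)")
  f <- spectrum@frequency
  sel <- which(f >= band[1] & f <= band[2])
  if (!length(sel))
    stop(sprintf("no spectral bins inside [%g, %g] Hz", band[1], band[2]))
  m <- spectrum@magnitude
  k <- sel[which.max(m[sel])]   # first max = lowest-frequency tie
  est <- f[k]
  if (interpolate && k > 1L && k < length(m)) {
    a <- m[k - 1]; b <- m[k]; cc <- m[k + 1]
    den <- a - 2 * b + cc
    if (den < 0) {  # genuine local maximum
      delta <- 0.5 * (a - cc) / den
      delta <- max(min(delta, 0.5), -0.5)
      est <- est + delta * spectrum@resolution
    }
  }
  est <- max(min(est, band[2]), band[1])
  FrequencyEstimate(frequency = est, peakMagnitude = m[k],
                    binResolution = spectrum@resolution, band = band,
                    provenance = c(spectrum@provenance,
                                   list(interpolated = interpolate)))
}

#' Recover the respiratory rate from an acquisition
#'
#' The full recovery chain: slice the intensity-time section at the laser
#' line, remove the linear trend, smooth with a moving average, transform
#' (zero-padded DFT), and pick the dominant in-band frequency with parabolic
#' refinement. All parameters are logged into the estimate's provenance.
#'
#' @inheritParams extractWaveform
#' @inheritParams movingAverage
#' @inheritParams dftSpectrum
#' @inheritParams pickFrequency
#' @return a \linkS4class{FrequencyEstimate}; `estimatedBpm()` gives the
#'   rate in breaths per minute
#' @examples
#' sp <- simulateAcquisition(MotionSpec(0.3291, displacement = 2),
#'                           noise = zeroNoise())
#' est <- recoverRate(sp)
#' estimatedHz(est)
#' @export
recoverRate <- function(spectra, center = 632, bandHalfwidth = 2,
                        window = 3, band = c(0.05, 2.5),
                        zeroPadFactor = 4, interpolate = TRUE) {
  wave <- extractWaveform(spectra, center = center,
                          bandHalfwidth = bandHalfwidth)
  wave <- detrendWaveform(wave)
  wave <- movingAverage(wave, window = window)
  spec <- dftSpectrum(wave, zeroPadFactor = zeroPadFactor)
  pickFrequency(spec, band = band, interpolate = interpolate)
}
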