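---
title: "Methods: simulating and recovering a laser-spectroscopic respiratory rate"
author: "respirolaser"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and recovering a laser-spectroscopic respiratory rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respirolaser)
```

## The measurement principle

A striped card (black bars on a white field) rides on a surface that
oscillates vertically — a mechanical stage in calibration, the chest wall in
use. A low-power laser illuminates a fixed spot; a fibre-coupled
spectrometer records the reflected spectrum frame by frame. As the card
moves, the dark bar sweeps through the spot and modulates the reflected
power at the laser line, so the intensity-time section at that wavelength is
a surrogate for the displacement waveform, and its dominant Fourier
component is the oscillation (breathing) frequency. The package implements
both directions: a physics-based forward model that renders such recordings
synthetically, and the recovery pipeline that turns any such recording —
simulated or exported from a real instrument — back into a rate.

## Forward model

**Motion.** The displacement is
$b(t) = b_{\max}\,\sin(2\pi f t + \varphi)$ with $b_{\max}$ half the
peak-to-peak travel: the stage moves between two stops spaced by the
configured displacement (1–5 cm, spanning the ~1.2 cm of normal adult
breathing up to the 4–5 cm of irregular excursions). A triangle waveform
(constant-speed travel, what a constant-RPM stepper actually produces) is
available; both waveforms share period and range, and the pipeline must
recover the same fundamental from either. Sampling requires
`sampleRate > 2f`; violations raise an error naming both rates.

**The condition grid.** `calibrationGrid()` embeds the 35 calibrated stage
frequencies (7 motor speeds 10–70 RPM × 5 displacements 1–5 cm,
0.06993–2.286 Hz) as printed constants. They are deliberately *not*
recomputed from the kinematics: `nominalFrequency(rpm, step, lead)` with the
best-fitting lead of 4 cm/rotation reproduces most cells
(`nominalFrequency(10, 1)` = 0.333 Hz) but deviates for others (the (10 RPM,
4 cm) cell is 0.0833 Hz nominal against 0.07683 Hz calibrated), because the
real stage's ramping is not captured by a single lead constant. The grid is
therefore authoritative and the kinematic formula a design convenience.

**Card and spot.** The card is a 1D piecewise-constant reflectance field
along the travel axis (white 0.90, black 0.05, zero off-card): the stripes
span the card width, so the transverse dimension integrates out. The
circular 2 mm spot reduces to a chord-weighted 1D kernel; for a top-hat disc
the kernel CDF is analytic,
$W(u) = \tfrac{u\sqrt{r^2-u^2} + r^2\arcsin(u/r)}{\pi r^2} + \tfrac12$, and
the reflected fraction is an exact weighted sum over the field's segments —
no quadrature. A gaussian profile (diameter read as intensity FWHM) uses the
normal CDF the same way. Both are validated in the tests against a
brute-force rasterized 2D disc oracle. The 15° source tilt of a real bench
only keeps the reflection inside the collection cone; it is absorbed into a
`geometryFactor` (card-relative spot travel per unit platform travel,
default 1).

**Bar placement.** Where the dark bar sits relative to the travel is the one
genuinely open geometric choice, and it decides whether the method works.
A bar at mid-travel is crossed twice per cycle at even spacing, so the
reflected signal's fundamental is $2f$, not $f$. A bar between mid-travel
and the stop is crossed twice per cycle at uneven spacing; that restores a
component at $f$, but each crossing is a narrow dip (the spot clears the bar
in well under one 0.1 s frame at the larger displacements), and the dip
train's harmonics and their aliases overwhelm the fundamental — in our
numerical experiments most grid conditions then recover a wrong frequency.
The default (`defaultCardFor()`) therefore centres the bar **at the lower
turning point of the travel**: the spot reaches the bar once per cycle and
dwells there while the velocity passes through zero, producing one smooth,
wide reflectance dip per period. Its fundamental is $f$, its harmonics decay
quickly, and every grid condition — including 2.286 Hz sampled at 10 Hz —
is recovered within a fraction of a DFT bin. This mirrors the physical
set-up in which the spot sits on the bar at full exhalation.

**Spectral rendering and noise.** Each frame is a dark baseline
(150 counts) plus a Gaussian line at 632.8 nm whose peak is
`integrationScale` (10 000 counts) times the reflected fraction, on a
3648-pixel 345–1040 nm grid at 10 frames/s — the footprint of a compact CCD
spectrometer. The line's 1.5 nm FWHM is instrument broadening (a few pixels);
a He-Ne line is far narrower, but the pipeline averages a ±2 nm band, so
only the band-integrated amplitude matters. The noise model adds Gaussian
read noise (SD 200 counts = 2% of peak), signal-proportional shot noise
(2%), and a slow sinusoidal baseline drift (500 counts = 5% of peak, 120 s
period, random phase) common to all pixels of a frame, then clamps at the
physical floor of zero. A seeded `NoiseModel` is bit-reproducible and leaves
the caller's RNG stream untouched. Per-condition record length defaults to
60 s — long enough for four cycles of the slowest grid condition and a
1/60 Hz raw resolution, short enough that the 105-recording campaign runs in
about a minute.

**What the generator does and does not emulate.** It reproduces the
signal-chain structure of a real recording: a non-sinusoidal periodic
modulation riding on a large DC level, detector noise, and slow drift. It
does not model speckle, polarization, inhomogeneous bar printing, stage
acceleration profiles, integration-time blur, wavelength-calibration error,
or body-movement artefacts. Passing tests therefore demonstrate that the
recovery chain is correct and robust against the modelled noise — not that
a physical instrument will reach the same uncertainty, which on real
hardware is dominated by exactly the unmodelled imperfections. Consistent
with that, the simulated campaign's mean uncertainty (computed by the
acceptance script) sits well below the few-percent level a bench
measurement reports.

## Recovery pipeline

`recoverRate()` composes five steps, each exported separately:

1. **Slice** (`extractWaveform`): per-frame mean over wavelength bins within
   ±2 nm of 632 nm. Averaging ~21 pixels beats single-pixel extraction by
   √21 in noise for a line wider than one pixel.
2. **Detrend** (`detrendWaveform`): subtract the least-squares line in time.
   This removes the DC level and linearises away the slow drift so the
   spectral search band need not dodge a huge zero-frequency peak. The
   affine part is annihilated exactly; a finite record also loses the
   $O(1/n)$ projection of the tone itself onto the trend basis, a bias far
   below one bin.
3. **Smooth** (`movingAverage`): centred 3-sample window (0.3 s at 10 Hz).
   Its first spectral null is at 3.3 Hz, safely above the highest
   physiological frequency in the grid (2.286 Hz), so the passband is
   untouched while frame-to-frame noise drops by ~1/3 in variance. Edges
   shrink the window symmetrically rather than padding zeros, which would
   bias short records; a constant signal passes through exactly, and
   window 1 is the identity.
4. **Transform** (`dftSpectrum`): zero-padded (factor 4) magnitude DFT on
   the non-negative half-axis. Padding interpolates the spectrum (bin
   0.0042 Hz for a 60 s record) without changing energy; Parseval's
   identity against the full two-sided transform is tested to 1e-6.
5. **Pick** (`pickFrequency`): arg-max magnitude in the closed band
   0.05–2.5 Hz (all physiological rates with margin, DC excluded by the band
   floor plus detrending), refined by a three-point parabolic fit through
   the peak bin when it is a genuine local maximum; the refinement is
   clamped to ±half a bin and exact ties break toward the lower frequency —
   the conservative choice, since harmonics sit above the fundamental.

Zero padding plus parabolic refinement is the standard sub-bin estimator
pair; neither is prescribed by the measurement principle itself, so both are
switchable (`zeroPadFactor`, `interpolate`).

## Evaluation

`absoluteUncertainty()` is the accuracy metric
$100\,|f_{\text{est}} - f_{\text{true}}|/f_{\text{true}}$ — scale-invariant,
zero exactly at equality. `classifyRate()` labels frequencies against the
closed normal band [0.1, 1] Hz (6–60 bpm); endpoints are inclusive, a choice
that is observationally neutral on the grid (no grid frequency equals an
endpoint) but keeps 60 bpm "normal", matching clinical convention.
`confusionMetrics()` treats abnormal as the positive class and reports any
zero-denominator ratio as `NA`, never 0. `runGrid()` ties it together:
35 conditions × `repeats` recordings, per-recording seeds drawn once from
the master seed, aggregated per displacement (mean ± SD) and overall, plus
the confusion table of normal/abnormal calls.

## Numerical and interface choices

* Analytic kernel CDFs make the overlap exact and fast; the rasterized
  oracle lives only in the tests.
* Frames are written as per-frame TSV (17 significant digits, so text round
  trips are bit-exact, `#`-prefixed headers carrying frame index, time and
  ISO timestamp) — greppable and close to vendor exports; the cube format is
  a single serialized RDS container for lossless fast round trips. Both feed
  the same pipeline, and timestamps fall back to a uniform axis at a stated
  rate when absent.
* The time axis must be uniform to 1e-9 s; non-uniform records are rejected
  at the transform rather than silently resampled.
* The run configuration is one flat YAML document; omitted keys take class
  defaults, and omitting the card keys selects the motion-dependent default
  card.
* Problem sizes in the test suite: unit tests run on a reduced 128-point
  wavelength grid around the line; the end-to-end checks use the full
  3648-point grid, 60 s records, and the complete 35 × 3 campaign.

## Known limitations

* Single-rate estimation only: no instantaneous-rate tracking, no
  harmonic disambiguation beyond band-limited arg-max with lower-frequency
  tie-breaks (a strong second harmonic inside the band could in principle
  win for pathological waveforms).
* The normal band and search band are fixed intervals; no subject-specific
  adaptation.
* The simulator's noise is stationary and Gaussian; real campaigns add
  power drift, card inhomogeneity and patient motion, so simulated
  uncertainties are a lower bound in spirit even though the package never
  claims hardware-level numbers.
* `readFrames()` expects the package's own export layout (or one matching
  it); proprietary vendor binaries are out of scope.
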