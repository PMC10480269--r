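# respirolaser

Respiratory rate is a first-line vital sign, yet the standard ways of
measuring it — adhesive electrodes, impedance belts, capnometry — touch the
patient, which is exactly what you want to avoid with preterm neonates and
long-term intensive-care monitoring. One non-contact alternative points a
low-power laser at a black/white striped card riding on the chest wall and
watches the reflected intensity with a fibre-coupled spectrometer: as the
card oscillates under the beam, the reflected power at the laser line is
modulated at the breathing frequency, and a Fourier transform of that
intensity-time trace reads the rate off directly.

`respirolaser` is a simulator and analysis pipeline for that measurement
principle, aimed at people designing or validating such optical rate
monitors. It provides, Bioconductor-style (S4 classes around a
`SummarizedExperiment` core):

* a **forward model** — chest-wall motion
  `b(t) = b_max sin(2π f t + φ)` (or a constant-speed triangle), a 1D
  reflectance field for the striped card, a chord-weighted overlap model for
  the circular laser spot, and a spectral renderer that turns the reflected
  fraction into time-resolved spectrometer frames with read noise, shot
  noise and baseline drift;
* a **recovery pipeline** — slice the intensity-time section at 632 nm,
  detrend, moving-average smooth, zero-padded DFT
  `B(ω) = ∫ b(t) e^{-jωt} dt`, and pick the dominant peak in the
  physiological band (0.05–2.5 Hz) with parabolic sub-bin interpolation;
* an **evaluation layer** — the percent absolute uncertainty
  `100 · |f_est − f_true| / f_true`, classification against the normal
  respiratory band 0.1–1 Hz (6–60 bpm), confusion metrics with abnormal as
  the positive class, and a grid experiment driver reproducing the embedded
  35-condition stage calibration (7 motor speeds × 5 displacements,
  0.06993–2.286 Hz, 7 abnormal conditions).

## Worked example

Simulate one minute of a 0.3291 Hz breathing motion (the 20 RPM / 2 cm
condition of the calibration grid) and recover the rate:

```r
library(respirolaser)

spec <- MotionSpec(frequency = 0.3291, displacement = 2, duration = 60)
acq  <- simulateAcquisition(spec, noise = NoiseModel(seed = 42L))
acq
#> TimeResolvedSpectra: 600 frames x 3648 wavelengths
#>   time 0-59.9 s at 10 Hz; wavelengths 345-1040 nm
#>   simulated motion at 0.3291 Hz

est <- recoverRate(acq)
est
#> FrequencyEstimate: 0.3290 Hz (19.74 bpm), bin 0.004167 Hz, band [0.05, 2.5] Hz

absoluteUncertainty(estimatedHz(est), 0.3291)   # percent
#> 0.035
classifyRate(estimatedHz(est))
#> [1] "normal"
```

The 600 frames are the 60 s record at the 10 Hz frame rate; the recovered
0.3290 Hz (19.74 breaths/min) sits 0.035% from the true stage frequency,
well inside one interpolated DFT bin (0.0042 Hz), and is correctly labelled
a normal rate. `runGrid()` repeats this over all 35 stage conditions and
aggregates uncertainties per displacement plus the normal/abnormal confusion
metrics; `writeGridReport()` writes the per-recording and summary tables.

A thin command-line front end (`inst/scripts/respirolaser`) exposes
`simulate`, `convert` (per-frame TSV ↔ single-file cube), `recover` and
`grid` subcommands over the same functions.

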