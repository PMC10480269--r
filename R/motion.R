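# motion value at time t (cm, relative to mid-travel)
motionValue <- function(spec, t) {
  theta <- 2 * pi * spec@frequency * t + spec@phase
  amp <- spec@displacement / 2
  switch(spec@waveform,
    sine = amp * sin(theta),
    triangle = amp * (2 / pi) * asin(sin(theta)))
}

checkNyquist <- function(sampleRate, frequency) {
  if (sampleRate <= 2 * frequency)
    stop(sprintf(paste0("sampling rate %g Hz violates the Nyquist criterion",
                        " for motion at %g Hz (need > %g Hz)"),
                 sampleRate, frequency, 2 * frequency))
  invisible(TRUE)
}

#' Sample a displacement waveform
#'
#' Samples the platform (chest-wall) displacement
#' \eqn{b(t) = b_{max}\sin(2\pi f t + \phi)} — or its constant-speed triangle
#' counterpart — on a uniform time grid. \eqn{b_{max}} is half the
#' peak-to-peak displacement.
#'
#' @param spec a \linkS4class{MotionSpec}
#' @param sampleRate sampling rate in Hz; must exceed twice `spec@frequency`
#' @return a `data.frame` with columns `time_s` and `displacement_cm`,
#'   `floor(duration * sampleRate)` rows, starting at `t = 0`.
#' @examples
#' ds <- displacementSeries(MotionSpec(0.25, displacement = 2), 10)
#' head(ds)
#' @export
displacementSeries <- function(spec, sampleRate) {
  stopifnot(is(spec, "MotionSpec"))
  validObject(spec)
  checkNyquist(sampleRate, spec@frequency)
  n <- floor(spec@duration * sampleRate)
  t <- (seq_len(n) - 1) / sampleRate
  data.frame(time_s = t, displacement_cm = motionValue(spec, t))
}

# Table of platform frequencies: 7 motor speeds (rpm) x 5 displacements (cm).
# Values are embedded constants, row-major by rpm. Frequencies outside the
# 0.1-1 Hz normal band are the abnormal (pathological-rate) conditions.
.calibrationTable <- local({
  f <- c(0.333,  0.1655, 0.1101, 0.07683, 0.06993,
         0.6666, 0.3291, 0.2196, 0.1703,  0.1396,
         0.9876, 0.4828, 0.3381, 0.2491,  0.2115,
         1.31,   0.6474, 0.4348, 0.3318,  0.279,
         1.6,    0.8046, 0.5673, 0.4094,  0.3322,
         1.861,  0.9584, 0.6931, 0.4971,  0.4094,
         2.286,  1.111,  0.793,  0.5785,  0.4633)
  data.frame(rpm = rep(seq(10, 70, by = 10), each = 5),
             step_cm = rep(1:5, times = 7),
             frequency_hz = f)
})

#' The 35-condition calibration grid
#'
#' The embedded table of platform oscillation frequencies realised by the
#' mechanical stage: 7 motor speeds (10-70 RPM by 10) crossed with 5
#' peak-to-peak displacements (1-5 cm by 1). The frequencies are printed
#' constants measured on the stage, not recomputed from a kinematic model
#' (see [nominalFrequency()] for the approximate model). Exactly 7 of the 35
#' frequencies fall outside the `[0.1, 1]` Hz normal respiratory band and are
#' flagged abnormal.
#'
#' @param normalBand closed frequency interval regarded as normal, Hz
#' @return a `data.frame` with 35 rows and columns `rpm`, `step_cm`,
#'   `frequency_hz`, `is_abnormal`.
#' @examples
#' g <- calibrationGrid()
#' sum(g$is_abnormal)     # 7
#' max(g$frequency_hz)    # 2.286
#' @export
calibrationGrid <- function(normalBand = c(0.1, 1.0)) {
  g <- .calibrationTable
  g$is_abnormal <- g$frequency_hz < normalBand[1] |
    g$frequency_hz > normalBand[2]
  g
}

#' Nominal stage frequency from motor speed
#'
#' Approximate kinematic model of the stage: a lead screw advancing
#' `lead` cm per rotation at `rpm` rotations per minute, oscillating over a
#' peak-to-peak travel of `step` cm, completes `rpm * lead / (60 * 2 * step)`
#' cycles per second. This is a convenience for designing new conditions;
#' the measured grid ([calibrationGrid()]) deviates from it for some cells (the
#' real stage's ramping is not modelled), so the grid is never validated
#' against this formula.
#'
#' @param rpm motor speed, rotations per minute
#' @param step peak-to-peak travel, cm
#' @param lead screw lead, cm per rotation
#' @return nominal oscillation frequency, Hz
#' @examples
#' nominalFrequency(10, 1)   # 0.333 Hz
#' @export
nominalFrequency <- function(rpm, step, lead = 4) {
  if (any(rpm <= 0) || any(step <= 0) || any(lead <= 0))
    stop("rpm, step and lead must all be positive")
  rpm * lead / (60 * 2 * step)
}

#' Read and write the condition grid
#'
#' The grid travels as a tab-delimited table with a header row and columns
#' `rpm`, `step_cm`, `frequency_hz`, `is_abnormal`.
#'
#' @param grid a grid `data.frame` as returned by [calibrationGrid()]
#' @param path file path
#' @return `readGrid()` returns the grid `data.frame`; `writeGrid()` returns
#'   `path` invisibly.
#' @export
writeGrid <- function(grid, path) {
  need <- c("rpm", "step_cm", "frequency_hz", "is_abnormal")
  stopifnot(all(need %in% names(grid)))
  utils::write.table(grid[need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeGrid
#' @export
readGrid <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("rpm", "step_cm", "frequency_hz", "is_abnormal")
  if (!all(need %in% names(g)))
    stop("grid file must have header columns: ", paste(need, collapse = ", "))
  g$is_abnormal <- as.logical(g$is_abnormal)
  g[need]
}
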