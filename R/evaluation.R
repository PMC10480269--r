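#' Percent absolute uncertainty
#'
#' The accuracy metric scoring a recovered frequency against its reference:
#' `100 * |estimated - true| / true`. Scale-invariant (both arguments in Hz
#' or both in bpm give the same percentage) and zero exactly at equality.
#'
#' @param estimated estimated frequency (Hz or bpm); vectorised
#' @param trueValue reference frequency in the same units; must be positive
#' @return percent absolute uncertainty, `>= 0`
#' @examples
#' absoluteUncertainty(0.34, 0.3291)
#' @export
absoluteUncertainty <- function(estimated, trueValue) {
  if (any(trueValue <= 0))
    stop("trueValue must be positive")
  100 * abs(estimated - trueValue) / trueValue
}

#' Classify a rate as normal or abnormal
#'
#' Frequencies inside the closed normal respiratory band (default
#' `[0.1, 1]` Hz, i.e. 6-60 breaths per minute) are `"normal"`; anything
#' outside is `"abnormal"` (pathological).
#'
#' @param frequency frequency (or frequencies), Hz; must be positive
#' @param normalBand closed interval regarded as normal, Hz
#' @return character vector of `"normal"` / `"abnormal"`
#' @examples
#' classifyRate(c(0.3291, 0.06993, 1.0))
#' @export
classifyRate <- function(frequency, normalBand = c(0.1, 1.0)) {
  if (length(normalBand) != 2L || normalBand[1] >= normalBand[2])
    stop("normalBand must be an increasing interval c(lo, hi)")
  if (any(frequency <= 0))
    stop("frequency must be positive")
  ifelse(frequency >= normalBand[1] & frequency <= normalBand[2],
         "normal", "abnormal")
}

#' Confusion metrics for rate classification
#'
#' Tabulates predicted against true normal/abnormal labels with abnormal as
#' the positive class, and derives sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, positive predictivity `tp/(tp+fp)` and accuracy
#' `(tp+tn)/n`. A ratio with a zero denominator is reported as `NA`, never
#' as 0.
#'
#' @param predicted,truth character vectors of `"normal"` / `"abnormal"`,
#'   equal length
#' @return a \linkS4class{ConfusionMetrics}
#' @export
confusionMetrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  lv <- c("normal", "abnormal")
  if (!all(predicted %in% lv) || !all(truth %in% lv))
    stop("labels must be 'normal' or 'abnormal'")
  tp <- sum(predicted == "abnormal" & truth == "abnormal")
  fp <- sum(predicted == "abnormal" & truth == "normal")
  tn <- sum(predicted == "normal" & truth == "normal")
  fn <- sum(predicted == "normal" & truth == "abnormal")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  new("ConfusionMetrics", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn),
      sensitivity = ratio(tp, tp + fn),
      specificity = ratio(tn, tn + fp),
      positivePredictivity = ratio(tp, tp + fp),
      accuracy = ratio(tp + tn, length(truth)))
}

#' Run the full grid experiment
#'
#' Simulates and scores every condition of the 35-entry calibration grid
#' ([calibrationGrid()]), `repeats` times each: simulate the acquisition, recover
#' the frequency, score it with the percent absolute uncertainty and
#' classify it against the normal band. Per-recording noise seeds are drawn
#' from `seed`, so the whole experiment is reproducible and independent of
#' the caller's RNG state.
#'
#' @param repeats recordings per condition
#' @param noise a \linkS4class{NoiseModel}; its `seed` slot is overridden
#'   per recording
#' @param seed master seed for the experiment
#' @param duration record length per recording, seconds
#' @param spot,cfg optics and spectrometer settings
#' @param normalBand closed normal respiratory band, Hz
#' @param ... further arguments passed to [recoverRate()]
#' @return a \linkS4class{GridReport}
#' @examples
#' \donttest{
#' rep <- runGrid(repeats = 1, noise = zeroNoise(), seed = 1, duration = 30)
#' overallUncertainty(rep)
#' }
#' @export
runGrid <- function(repeats = 3, noise = NoiseModel(), seed = 1,
                    duration = 60, spot = LaserSpot(),
                    cfg = SpectrometerConfig(),
                    normalBand = c(0.1, 1.0), ...) {
  stopifnot(repeats >= 1)
  grid <- calibrationGrid(normalBand)
  n <- nrow(grid) * repeats
  runSeeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  rows <- vector("list", n)
  i <- 0L
  for (r in seq_len(repeats)) {
    for (g in seq_len(nrow(grid))) {
      i <- i + 1L
      spec <- MotionSpec(frequency = grid$frequency_hz[g],
                         displacement = grid$step_cm[g],
                         duration = duration,
                         label = sprintf("rpm%d_step%d_rep%d",
                                         grid$rpm[g], grid$step_cm[g], r))
      nm <- noise
      nm@seed <- runSeeds[i]
      sp <- simulateAcquisition(spec, spot = spot, cfg = cfg, noise = nm)
      est <- recoverRate(sp, ...)
      fhat <- estimatedHz(est)
      rows[[i]] <- data.frame(
        rpm = grid$rpm[g], step_cm = grid$step_cm[g], repeat_idx = r,
        true_hz = grid$frequency_hz[g], estimated_hz = fhat,
        uncertainty_pct = absoluteUncertainty(fhat, grid$frequency_hz[g]),
        true_class = classifyRate(grid$frequency_hz[g], normalBand),
        predicted_class = classifyRate(fhat, normalBand))
    }
  }
  results <- do.call(rbind, rows)
  perDisp <- do.call(rbind, lapply(split(results, results$step_cm),
    function(d) data.frame(step_cm = d$step_cm[1],
                           mean_uncertainty_pct = mean(d$uncertainty_pct),
                           sd_uncertainty_pct = stats::sd(d$uncertainty_pct),
                           n = nrow(d))))
  rownames(perDisp) <- NULL
  cm <- confusionMetrics(results$predicted_class, results$true_class)
  new("GridReport", results = results, perDisplacement = perDisp,
      overall = mean(results$uncertainty_pct), confusion = cm,
      parameters = list(repeats = repeats, seed = seed,
                        duration_s = duration,
                        normal_band_hz = normalBand,
                        noise = list(read_noise_sd = noise@readNoiseSd,
                                     shot_noise_scale = noise@shotNoiseScale,
                                     drift_amplitude = noise@driftAmplitude,
                                     drift_period_s = noise@driftPeriod)))
}

#' Write a grid report to disk
#'
#' Emits `grid_report.tsv` (one row per recording) and `summary.tsv`
#' (per-displacement aggregates, the overall mean uncertainty, and the four
#' confusion metrics) into a directory.
#'
#' @param report a \linkS4class{GridReport}
#' @param directory output directory (created if absent)
#' @return invisibly, the two file paths
#' @export
writeGridReport <- function(report, directory) {
  stopifnot(is(report, "GridReport"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  f1 <- file.path(directory, "grid_report.tsv")
  utils::write.table(gridResults(report), f1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cm <- gridConfusion(report)
  summ <- displacementSummary(report)
  extra <- data.frame(
    step_cm = NA_real_,
    mean_uncertainty_pct = overallUncertainty(report),
    sd_uncertainty_pct = stats::sd(gridResults(report)$uncertainty_pct),
    n = nrow(gridResults(report)))
  f2 <- file.path(directory, "summary.tsv")
  con <- file(f2, "w")
  utils::write.table(rbind(summ, extra), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c("",
    sprintf("overall_mean_uncertainty_pct\t%.6g", overallUncertainty(report)),
    sprintf("sensitivity\t%.6g", sensitivity(cm)),
    sprintf("specificity\t%.6g", specificity(cm)),
    sprintf("positive_predictivity\t%.6g", positivePredictivity(cm)),
    sprintf("accuracy\t%.6g", accuracy(cm))), con)
  close(con)
  invisible(c(f1, f2))
}
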