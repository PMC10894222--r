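#' Generate a noisy vibration stimulus
#'
#' Constructs a vibration velocity trace by stringing together independent
#' zero-mean Gaussian velocity samples at 1 kHz. The perceptually relevant
#' intensity of such a stimulus is its mean absolute speed, which for a
#' zero-mean Gaussian process equals \eqn{\sigma\sqrt{2/\pi}}.
#'
#' @param sigma Standard deviation of the generating Gaussian, in mm/s.
#' @param duration_ms Stimulus duration in ms. The trace has
#'   `floor(duration_ms * sample_rate_khz)` samples.
#' @param rng_seed Integer seed; a fixed seed reproduces the trace exactly.
#' @param sample_rate_khz Sampling rate in kHz (fixed at 1 in the task design).
#'
#' @return An object of class `"vibration_stimulus"`: a list with
#'   `velocity_trace` (mm/s), `duration_T` (ms), `nominal_sigma` (mm/s),
#'   `nominal_intensity` (\eqn{\sigma\sqrt{2/\pi}}, mm/s) and `seed_id`.
#' @examples
#' v <- generate_vibration(sigma = 100, duration_ms = 500, rng_seed = 1)
#' mean(abs(v$velocity_trace))   # close to 100 * sqrt(2/pi) = 79.8 mm/s
#' @export
generate_vibration <- function(sigma, duration_ms, rng_seed = 1L,
                               sample_rate_khz = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number (mm/s)")
  if (!is.numeric(duration_ms) || length(duration_ms) != 1L ||
      !is.finite(duration_ms) || duration_ms < 1)
    stop("'duration_ms' must be a single number >= 1 (ms)")
  n <- floor(duration_ms * sample_rate_khz)
  trace <- withr_seed(rng_seed, stats::rnorm(n, mean = 0, sd = sigma))
  structure(
    list(velocity_trace = trace,
         duration_T = duration_ms,
         nominal_sigma = sigma,
         nominal_intensity = sigma * sqrt(2 / pi),
         seed_id = as.integer(rng_seed)),
    class = "vibration_stimulus")
}

#' @export
print.vibration_stimulus <- function(x, ...) {
  cat(sprintf(
    "Vibration stimulus: T = %g ms, sigma = %g mm/s (I = %.1f mm/s), %d samples, seed %d\n",
    x$duration_T, x$nominal_sigma, x$nominal_intensity,
    length(x$velocity_trace), x$seed_id))
  invisible(x)
}

#' Normalized duration and intensity differences
#'
#' The two stimuli of a trial are compared through normalized indices,
#' \eqn{\Delta T = (T_2 - T_1)/(T_2 + T_1)} and
#' \eqn{\Delta I = (I_2 - I_1)/(I_2 + I_1)}. Both are dimensionless, bounded
#' in (-1, 1), antisymmetric under swapping the stimuli, and zero when the
#' two stimuli match.
#'
#' @param T1,T2 Durations in ms (positive).
#' @param I1,I2 Intensities in mm/s (positive).
#' @return Numeric index, vectorized over its arguments.
#' @examples
#' delta_T(334, 694)  # 0.35, the extreme of the duration design
#' delta_I(64, 119)   # 0.30, the extreme of the intensity design
#' @export
delta_T <- function(T1, T2) {
  if (any(!is.finite(T1)) || any(!is.finite(T2)) || any(T1 <= 0) || any(T2 <= 0))
    stop("durations 'T1' and 'T2' must be positive and finite")
  (T2 - T1) / (T2 + T1)
}

#' @rdname delta_T
#' @export
delta_I <- function(I1, I2) {
  if (any(!is.finite(I1)) || any(!is.finite(I2)) || any(I1 <= 0) || any(I2 <= 0))
    stop("intensities 'I1' and 'I2' must be positive and finite")
  (I2 - I1) / (I2 + I1)
}

#' Seven log-spaced comparison levels between two printed extremes
#'
#' The task design spaces the comparison durations and intensities
#' logarithmically; only the extremes and the reference are printed, so the
#' intermediate levels are generated as a geometric series. The geometric
#' mean of the extremes recovers the reference (334 ms, 64 mm/s).
#'
#' @param lo,hi Extremes of the series.
#' @param n Number of levels (default 7, the psychometric design).
#' @return Numeric vector of length `n`.
#' @export
design_levels <- function(lo, hi, n = 7L) {
  stopifnot(lo > 0, hi > lo, n >= 2)
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Congruence of the two stimulus features
#'
#' A trial is congruent when the irrelevant feature difference pushes in the
#' same direction as the relevant one (sign(dT) * sign(dI) > 0), incongruent
#' when they oppose, and neutral when either index is zero.
#'
#' @param dT,dI Normalized duration and intensity differences.
#' @return Character vector: `"congruent"`, `"incongruent"` or `"neutral"`.
#' @export
congruence_label <- function(dT, dI) {
  s <- sign(dT) * sign(dI)
  ifelse(s > 0, "congruent", ifelse(s < 0, "incongruent", "neutral"))
}

#' Enumerate the two-interval trial design
#'
#' Builds the stimulus generalization matrix of a delayed comparison session:
#' every combination of comparison duration and intensity against the fixed
#' reference stimulus 1, labeled with the normalized indices, congruence and
#' light condition. Defaults reproduce the psychometric design: T1 = 334 ms
#' with seven log-spaced T2 between 161 and 694 ms, and I1 = 64 mm/s with
#' seven log-spaced I2 between 34 and 119 mm/s.
#'
#' @param task `"duration"` or `"intensity"`: which feature is relevant.
#' @param durations Comparison (stimulus 2) durations in ms.
#' @param intensities Comparison (stimulus 2) intensities in mm/s.
#' @param reference_T,reference_I Stimulus 1 duration (ms) and intensity (mm/s).
#' @param light_condition One of `"none"`, `"excite_stim1"`, `"excite_stim2"`,
#'   `"inhibit_stim2"`, `"external_led"`.
#' @return A data frame with one row per trial type and columns
#'   `T1, T2, I1, I2, delta_T, delta_I, light, congruence, task`.
#' @examples
#' design <- build_trial_matrix("duration")
#' range(design$delta_T)   # -0.35 .. 0.35
#' @export
build_trial_matrix <- function(task = c("duration", "intensity"),
                               durations = design_levels(161, 694),
                               intensities = design_levels(34, 119),
                               reference_T = 334, reference_I = 64,
                               light_condition = "none") {
  task <- match.arg(task)
  light_condition <- match.arg(
    light_condition,
    c("none", "excite_stim1", "excite_stim2", "inhibit_stim2", "external_led"))
  if (!length(durations) || !length(intensities))
    stop("'durations' and 'intensities' must be non-empty")
  if (any(durations <= 0) || any(intensities <= 0) ||
      reference_T <= 0 || reference_I <= 0)
    stop("durations and intensities must be positive")
  # stimuli are delivered at 1-ms resolution and nominal intensities are
  # labeled in whole mm/s (the rounded middle level recovers the reference)
  durations <- round(durations)
  reference_T <- round(reference_T)
  intensities <- round(intensities)
  reference_I <- round(reference_I)
  grid <- expand.grid(T2 = durations, I2 = intensities,
                      KEEP.OUT.ATTRS = FALSE)
  dT <- delta_T(reference_T, grid$T2)
  dI <- delta_I(reference_I, grid$I2)
  data.frame(
    T1 = reference_T, T2 = grid$T2, I1 = reference_I, I2 = grid$I2,
    delta_T = dT, delta_I = dI,
    light = light_condition,
    congruence = congruence_label(dT, dI),
    task = task,
    stringsAsFactors = FALSE)
}

#' Write / read vibration stimuli as plain CSV
#'
#' One row per sample with columns `time_ms, velocity_mm_s`; metadata kept in
#' a `# key: value` comment header.
#'
#' @param stim A `"vibration_stimulus"`.
#' @param path File path.
#' @return `read_vibration_csv` returns a `"vibration_stimulus"`.
#' @export
write_vibration_csv <- function(stim, path) {
  stopifnot(inherits(stim, "vibration_stimulus"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_T: %g", stim$duration_T), con)
  writeLines(sprintf("# nominal_sigma: %g", stim$nominal_sigma), con)
  writeLines(sprintf("# seed_id: %d", stim$seed_id), con)
  utils::write.csv(
    data.frame(time_ms = seq_along(stim$velocity_trace) - 1L,
               velocity_mm_s = stim$velocity_trace),
    con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vibration_csv
#' @export
read_vibration_csv <- function(path) {
  hdr <- readLines(path, n = 3L)
  meta <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    as.numeric(sub(".*: ", "", ln))
  }
  dat <- utils::read.csv(path, comment.char = "#")
  sigma <- meta("nominal_sigma")
  structure(
    list(velocity_trace = dat$velocity_mm_s,
         duration_T = meta("duration_T"),
         nominal_sigma = sigma,
         nominal_intensity = sigma * sqrt(2 / pi),
         seed_id = as.integer(meta("seed_id"))),
    class = "vibration_stimulus")
}
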