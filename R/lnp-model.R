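#' Single-neuron parameter set for the LNP response model
#'
#' The linear-nonlinear-Poisson model of a vS1 unit: a constant background
#' current, a mechanoreceptor-derived current gated by the stimulus window,
#' an optogenetic current gated by the light window (with a post-light-offset
#' term expressing post-stimulation suppression or rebound), a generalized
#' sigmoid current-to-rate transfer, and Poisson spike emission.
#'
#' Currents are in arbitrary units (a.u.); the transfer function scales them
#' by a fixed factor of 10. Rates are in spikes per 1-ms bin. The decay time
#' constants default to the across-neuron medians tau_M = 48, tau_O = 49 and
#' tau_I = 28 ms and are treated as population-level constants; the current
#' onset times t0_M and t0_O are set by the experimenter (default 0 ms).
#'
#' @param I0 Background current (a.u.).
#' @param I1_ss,I1_peak Steady-state and peak mechanoreceptor currents (a.u.).
#' @param I2_ss,I2_peak Steady-state and peak optogenetic currents (a.u.).
#' @param I3_peak Post-light-offset current (a.u.; negative values express
#'   post-stimulation suppression).
#' @param lambda_max Maximum firing rate, spikes per 1-ms bin (> 0).
#' @param upsilon Nonlinearity scale of the generalized sigmoid (> 0).
#' @param tau_M,tau_O,tau_I Decay time constants in ms (> 0).
#' @param t0_M,t0_O Current onset times in ms.
#' @return An object of class `"neuron_params"` (a named list).
#' @examples
#' p <- neuron_params(I0 = -0.5, I1_ss = 0.6, I1_peak = 1.5, lambda_max = 0.08)
#' lnp_rate(p, t = 0:500, T = 334)
#' @export
neuron_params <- function(I0 = 0, I1_ss = 0, I1_peak = 0,
                          I2_ss = 0, I2_peak = 0, I3_peak = 0,
                          lambda_max = 0.05, upsilon = 1,
                          tau_M = 48, tau_O = 49, tau_I = 28,
                          t0_M = 0, t0_O = 0) {
  if (lambda_max <= 0) stop("'lambda_max' must be > 0")
  if (upsilon <= 0) stop("'upsilon' must be > 0")
  if (tau_M <= 0 || tau_O <= 0 || tau_I <= 0) stop("time constants must be > 0")
  structure(
    list(I0 = I0, I1_ss = I1_ss, I1_peak = I1_peak,
         I2_ss = I2_ss, I2_peak = I2_peak, I3_peak = I3_peak,
         lambda_max = lambda_max, upsilon = upsilon,
         tau_M = tau_M, tau_O = tau_O, tau_I = tau_I,
         t0_M = t0_M, t0_O = t0_O),
    class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("LNP neuron parameters (currents in a.u., rates in spikes/ms):\n")
  print(unlist(x))
  invisible(x)
}

# Names of the 8 parameters free in the fit / spanned by the mixture.
lnp_free_names <- c("I0", "I1_ss", "I1_peak", "I2_ss", "I2_peak", "I3_peak",
                    "lambda_max", "upsilon")

#' Stimulus window function
#'
#' Product of two logistic gates opening at `t0` and closing at `t0 + T`,
#' with a ~1 ms transition scale (time in ms):
#' `expit(t - t0) * expit(-(t - T - t0))`.
#'
#' @param t Time in ms (vectorized).
#' @param T Stimulus (or light) duration in ms.
#' @param t0 Gate onset time in ms.
#' @return Values in (0, 1).
#' @export
window_W <- function(t, T, t0 = 0) {
  expit(t - t0) * expit(-(t - T - t0))
}

#' Input currents of the LNP neuron
#'
#' `mechano_current` is the vibration-evoked current: an exponential decay
#' from `I1_peak` toward the steady state `I1_ss` with time constant `tau_M`,
#' gated by the stimulus window. `opto_current` is the light-evoked current:
#' the analogous gated decay (`I2_peak` to `I2_ss`, constant `tau_O`) plus a
#' post-light-offset current `I3_peak` decaying with `tau_I`, gated on after
#' light offset. `total_current` adds the background `I0`.
#'
#' @param t Time in ms (vectorized).
#' @param params A [neuron_params()] object.
#' @param T Stimulus duration in ms.
#' @param light Logical: is the optogenetic drive on for this condition?
#' @param light_T Light duration in ms (defaults to the stimulus duration).
#' @param light_t0 Light onset offset in ms relative to `t0_O` (the
#'   photoinhibition protocol starts the light 50 ms early).
#' @return Current in a.u., same length as `t`.
#' @export
mechano_current <- function(t, params, T) {
  decay <- params$I1_ss +
    (params$I1_peak - params$I1_ss) * exp(-(t - params$t0_M) / params$tau_M)
  decay * window_W(t, T, params$t0_M)
}

#' @rdname mechano_current
#' @export
opto_current <- function(t, params, T, light_T = T, light_t0 = 0) {
  t0 <- params$t0_O + light_t0
  decay <- params$I2_ss +
    (params$I2_peak - params$I2_ss) * exp(-(t - t0) / params$tau_O)
  gated <- decay * window_W(t, light_T, t0)
  post <- params$I3_peak * exp(-(t - light_T - t0) / params$tau_I) *
    expit(t - light_T - t0)
  gated + post
}

#' @rdname mechano_current
#' @export
total_current <- function(t, params, T, light = FALSE, light_T = T,
                          light_t0 = 0) {
  I <- params$I0 + mechano_current(t, params, T)
  if (light) I <- I + opto_current(t, params, T, light_T, light_t0)
  I
}

#' Current-to-rate transfer (I/F curve)
#'
#' Generalized sigmoid
#' \deqn{f = \lambda [1 - (1 + e^{10 I})^{-1/\upsilon}] + 10^{-4}}
#' mapping total input current to firing rate (spikes per 1-ms bin). The
#' current is always scaled by the constant factor 10 and the additive
#' constant 1e-4 is always applied; both stabilize fits in low-firing
#' neurons. The rate is monotone non-decreasing in the current for any
#' (lambda, upsilon).
#'
#' @param I_total Total input current in a.u. (vectorized).
#' @param params A [neuron_params()] object (uses `lambda_max`, `upsilon`).
#' @return Rate in spikes per 1-ms bin.
#' @export
rate_from_current <- function(I_total, params) {
  params$lambda_max *
    (1 - (1 / (1 + exp(10 * I_total)))^(1 / params$upsilon)) + 1e-4
}

#' Model firing-rate profile of a neuron under a condition
#'
#' @param params A [neuron_params()] object.
#' @param t Time in ms (vectorized); bins are 1 ms.
#' @param T Stimulus duration in ms.
#' @inheritParams total_current
#' @return Rate in spikes per 1-ms bin at each `t`.
#' @export
lnp_rate <- function(params, t, T, light = FALSE, light_T = T, light_t0 = 0) {
  rate_from_current(total_current(t, params, T, light, light_T, light_t0),
                    params)
}

#' Simulate Poisson spike rasters from an LNP neuron
#'
#' Per-bin spike counts are independent Poisson draws with mean equal to the
#' model rate at that bin; the total input current is the sum of background,
#' mechanoreceptor and (when the light is on) optogenetic currents.
#'
#' @param params A [neuron_params()] object.
#' @param T Stimulus duration in ms.
#' @param n_trials Number of independent trials.
#' @param light Logical, optogenetic drive on/off.
#' @param t_pre,t_post Baseline before onset and tail after offset, in ms.
#' @param rng_seed Integer seed.
#' @param intensity_gain Multiplier on the mechanoreceptor currents (used to
#'   express intensity coding; 1 = the fitted condition).
#' @inheritParams total_current
#' @return An object of class `"spike_raster"`: list with `counts`
#'   (n_trials x n_bins integer matrix), `time_ms` (bin left edges relative
#'   to stimulus onset), `bin_width` (1 ms), and the `condition` fields.
#' @export
simulate_spikes <- function(params, T, n_trials = 1L, light = FALSE,
                            t_pre = 0, t_post = 0, rng_seed = 1L,
                            intensity_gain = 1, light_T = T, light_t0 = 0) {
  stopifnot(n_trials >= 1, T > 0)
  time_ms <- seq.int(-t_pre, T + t_post - 1)
  p <- params
  if (intensity_gain != 1) {
    p$I1_ss <- p$I1_ss * intensity_gain
    p$I1_peak <- p$I1_peak * intensity_gain
  }
  rate <- lnp_rate(p, time_ms, T, light, light_T, light_t0)
  counts <- withr_seed(rng_seed, matrix(
    stats::rpois(n_trials * length(time_ms), rep(rate, each = n_trials)),
    nrow = n_trials))
  structure(
    list(counts = counts, time_ms = time_ms, bin_width = 1,
         rate = rate,
         condition = list(T = T, light = light,
                          intensity_gain = intensity_gain)),
    class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "Spike raster: %d trials x %d 1-ms bins (T = %g ms, light %s), mean rate %.1f spikes/s\n",
    nrow(x$counts), ncol(x$counts), x$condition$T,
    if (isTRUE(x$condition$light)) "on" else "off",
    1000 * mean(x$counts)))
  invisible(x)
}

#' Spike times from a raster
#'
#' Expands per-bin counts into per-trial event-time lists (ms, bin centers;
#' multiple spikes in a bin repeat the time).
#'
#' @param raster A `"spike_raster"`.
#' @return A list of numeric vectors, one per trial.
#' @export
spike_times <- function(raster) {
  mid <- raster$time_ms + raster$bin_width / 2
  apply(raster$counts, 1L, function(k) rep(mid, k), simplify = FALSE)
}

#' Write / read spike rasters as long-format CSV
#'
#' Columns `trial, time_ms, count`; zero-count bins are omitted. The time
#' axis and condition are kept in a `# key: value` header.
#'
#' @param raster A `"spike_raster"`.
#' @param path File path.
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# T: %g", raster$condition$T), con)
  writeLines(sprintf("# light: %d", as.integer(isTRUE(raster$condition$light))), con)
  writeLines(sprintf("# t_min: %g", min(raster$time_ms)), con)
  writeLines(sprintf("# t_max: %g", max(raster$time_ms)), con)
  writeLines(sprintf("# n_trials: %d", nrow(raster$counts)), con)
  idx <- which(raster$counts > 0, arr.ind = TRUE)
  dat <- data.frame(trial = idx[, 1L],
                    time_ms = raster$time_ms[idx[, 2L]],
                    count = raster$counts[idx])
  dat <- dat[order(dat$trial, dat$time_ms), ]
  utils::write.csv(dat, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 5L)
  meta <- function(key) as.numeric(sub(".*: ", "",
    grep(paste0("^# ", key, ":"), hdr, value = TRUE)))
  dat <- utils::read.csv(path, comment.char = "#")
  time_ms <- seq.int(meta("t_min"), meta("t_max"))
  n_trials <- as.integer(meta("n_trials"))
  counts <- matrix(0L, n_trials, length(time_ms))
  if (nrow(dat))
    counts[cbind(dat$trial, match(dat$time_ms, time_ms))] <- dat$count
  structure(
    list(counts = counts, time_ms = time_ms, bin_width = 1, rate = NULL,
         condition = list(T = meta("T"), light = meta("light") > 0,
                          intensity_gain = 1)),
    class = "spike_raster")
}
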