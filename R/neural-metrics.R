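#' Trial-averaged firing rate with a centered sliding window
#'
#' Average rate over trials, smoothed with a centered `window_ms` boxcar
#' shifting in 1-ms steps (edges use the valid part of the window).
#'
#' @param raster A `"spike_raster"`.
#' @param window_ms Sliding-window width, ms (default 40).
#' @return Numeric vector of rates in spikes/s on the raster's time axis.
#' @export
sliding_rate <- function(raster, window_ms = 40) {
  x <- colMeans(raster$counts)
  half <- floor(window_ms / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  1000 * (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Z-scored response of a single neuron
#'
#' The sliding-window rate is normalized by the neuron's spontaneous
#' activity, measured from `baseline_window` (default the 800 ms before
#' stimulus onset): the baseline mean rate is subtracted and the outcome is
#' divided by the baseline variance (the literal normalization used for the
#' reference displays; set `divisor = "sd"` for a conventional z-score).
#'
#' @param raster A `"spike_raster"` including pre-stimulus baseline.
#' @param baseline_window Length-2 vector, ms relative to onset (must
#'   precede it).
#' @param window_ms Sliding-window width for the rate estimate.
#' @param divisor `"variance"` (default) or `"sd"`.
#' @return A list: `time_ms`, `z`, `baseline_mean`, `baseline_var`,
#'   `excluded` (TRUE when the baseline variance is zero, in which case `z`
#'   is NA and the neuron should be dropped from z-scored pools).
#' @export
zscore_response <- function(raster, baseline_window = c(-800, 0),
                            window_ms = 40, divisor = c("variance", "sd")) {
  divisor <- match.arg(divisor)
  if (baseline_window[2L] > 0)
    stop("'baseline_window' must precede stimulus onset")
  rate <- sliding_rate(raster, window_ms)
  base <- rate[raster$time_ms >= baseline_window[1L] &
               raster$time_ms < baseline_window[2L]]
  if (!length(base)) stop("raster does not cover the baseline window")
  m <- mean(base); v <- stats::var(base)
  if (!is.finite(v) || v == 0) {
    warning("zero baseline variance; neuron flagged for exclusion")
    return(list(time_ms = raster$time_ms, z = rep(NA_real_, length(rate)),
                baseline_mean = m, baseline_var = v, excluded = TRUE))
  }
  denom <- if (divisor == "variance") v else sqrt(v)
  list(time_ms = raster$time_ms, z = (rate - m) / denom,
       baseline_mean = m, baseline_var = v, excluded = FALSE)
}

# Half-Gaussian kernel (peak at lag 0), truncated at 4 sigma, sum 1.
half_gaussian_kernel <- function(sigma) {
  s <- 0:ceiling(4 * sigma)
  k <- exp(-s^2 / (2 * sigma^2))
  k / sum(k)
}

# One-sided smoothing: "past" averages x(t - s), "future" averages x(t + s),
# renormalizing over the in-range kernel mass at the edges.
smooth_one_sided <- function(x, kern, side = c("past", "future")) {
  side <- match.arg(side)
  n <- length(x); m <- length(kern)
  out <- numeric(n)
  for (t in seq_len(n)) {
    s <- 0:(m - 1L)
    idx <- if (side == "past") t - s else t + s
    ok <- idx >= 1L & idx <= n
    out[t] <- sum(kern[ok] * x[idx[ok]]) / sum(kern[ok])
  }
  out
}

#' Boundary-aware population PSTH
#'
#' Averages the trial-mean rates of a set of neurons (1-ms steps) and
#' smooths with a half-Gaussian (sigma 25 ms by default) whose tail is
#' flipped at a boundary in the middle of the trace: before the flip the
#' kernel averages only earlier samples, after it only later samples. A
#' step response therefore contributes no smoothed mass before its onset
#' and none after its offset — the smoothing cannot leak response mass
#' across the stimulus boundaries.
#'
#' @param rasters A `"spike_raster"` or a list of them (same time axis);
#'   each raster's trial-averaged rate enters the population average.
#' @param smoothing_sigma Half-Gaussian sigma, ms.
#' @param flip_ms Boundary where the tail flips, ms; defaults to the middle
#'   of the time axis.
#' @param pool_edges When `TRUE`, returns only the first `pool_first` ms
#'   and final `pool_last` ms around the stimulus (the convention that
#'   allows pooling across durations), concatenated.
#' @param pool_first,pool_last Epoch lengths for `pool_edges`, ms.
#' @return An object of class `"psth_profile"`: `time_ms`, `rate`
#'   (spikes/s), `smoothing` descriptor.
#' @export
population_psth <- function(rasters, smoothing_sigma = 25, flip_ms = NULL,
                            pool_edges = FALSE, pool_first = 150,
                            pool_last = 50) {
  if (inherits(rasters, "spike_raster")) rasters <- list(rasters)
  time_ms <- rasters[[1L]]$time_ms
  rates <- vapply(rasters, function(r) {
    stopifnot(identical(r$time_ms, time_ms))
    1000 * colMeans(r$counts)
  }, numeric(length(time_ms)))
  avg <- rowMeans(rates)
  if (is.null(flip_ms)) flip_ms <- time_ms[ceiling(length(time_ms) / 2)]
  kern <- half_gaussian_kernel(smoothing_sigma)
  pre <- time_ms < flip_ms
  sm <- numeric(length(avg))
  sm[pre] <- smooth_one_sided(avg, kern, "past")[pre]
  sm[!pre] <- smooth_one_sided(avg, kern, "future")[!pre]
  out <- list(time_ms = time_ms, rate = sm,
              smoothing = list(type = "half-gaussian",
                               sigma_ms = smoothing_sigma,
                               flip_ms = flip_ms))
  if (pool_edges) {
    T <- rasters[[1L]]$condition$T
    sel <- (time_ms >= 0 & time_ms < pool_first) |
      (time_ms >= T - pool_last & time_ms < T)
    out$time_ms <- time_ms[sel]
    out$rate <- sm[sel]
  }
  structure(out, class = "psth_profile")
}

#' @export
print.psth_profile <- function(x, ...) {
  cat(sprintf(
    "Population PSTH: %d 1-ms bins, %s smoothing (sigma %g ms, flip at %g ms), peak %.1f spikes/s\n",
    length(x$time_ms), x$smoothing$type, x$smoothing$sigma_ms,
    x$smoothing$flip_ms, max(x$rate)))
  invisible(x)
}

#' Response onset and offset from a population PSTH
#'
#' Onset is the first upward crossing, and offset the last downward
#' crossing, of a threshold set `threshold_std` baseline standard
#' deviations above the baseline mean of the smoothed rate (baseline taken
#' 480 to 20 ms before stimulus onset by default). Crossings are localized
#' by linear interpolation between 1-ms samples. When the true stimulus
#' boundaries are supplied, detections more than `outlier_ms` from them are
#' flagged as outliers and invalidated.
#'
#' @param psth A `"psth_profile"` (or list with `time_ms`, `rate`).
#' @param threshold_std Threshold in baseline-STD units (default 2.2).
#' @param baseline_window Length-2 vector, ms relative to onset.
#' @param stim_T True stimulus duration for the outlier check (optional).
#' @param outlier_ms Outlier tolerance, ms (default 25).
#' @return An object of class `"onset_offset"`: `onset_ms`, `offset_ms`,
#'   `threshold` (rate units), `threshold_std`, `valid_onset`,
#'   `valid_offset`.
#' @export
detect_onset_offset <- function(psth, threshold_std = 2.2,
                                baseline_window = c(-480, -20),
                                stim_T = NULL, outlier_ms = 25) {
  t <- psth$time_ms; r <- psth$rate
  base <- r[t >= baseline_window[1L] & t < baseline_window[2L]]
  if (!length(base)) stop("PSTH does not cover the baseline window")
  thr <- mean(base) + threshold_std * stats::sd(base)
  search <- which(t >= baseline_window[2L])
  above <- r[search] > thr
  cross <- function(i, j) {
    # linear interpolation of the threshold crossing between samples i, j
    t[i] + (thr - r[i]) * (t[j] - t[i]) / (r[j] - r[i])
  }
  # crossings bounding the principal (longest) suprathreshold epoch, so
  # that isolated baseline noise excursions cannot masquerade as the
  # response onset or offset
  runs <- rle(above)
  onset <- offset <- NA_real_
  if (any(runs$values)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- which(runs$values)[which.max(runs$lengths[runs$values])]
    i0 <- starts[k]; i1 <- ends[k]
    onset <- if (i0 > 1L) cross(search[i0 - 1L], search[i0]) else t[search[1L]]
    offset <- if (i1 < length(above)) cross(search[i1], search[i1 + 1L])
              else NA_real_
  }
  valid_onset <- is.finite(onset)
  valid_offset <- is.finite(offset)
  if (!is.null(stim_T)) {
    if (valid_onset && abs(onset - 0) > outlier_ms) valid_onset <- FALSE
    if (valid_offset && abs(offset - stim_T) > outlier_ms) valid_offset <- FALSE
  }
  structure(list(onset_ms = onset, offset_ms = offset, threshold = thr,
                 threshold_std = threshold_std,
                 valid_onset = valid_onset, valid_offset = valid_offset),
            class = "onset_offset")
}

#' @export
print.onset_offset <- function(x, ...) {
  cat(sprintf(
    "Onset %s ms (%s), offset %s ms (%s); threshold %.2f spikes/s (%.1f STD)\n",
    format(round(x$onset_ms, 1)), if (x$valid_onset) "valid" else "invalid",
    format(round(x$offset_ms, 1)), if (x$valid_offset) "valid" else "invalid",
    x$threshold, x$threshold_std))
  invisible(x)
}

#' Population firing rate in the final window of the stimulus
#'
#' The rate-code probe: mean population rate during the final `window_ms`
#' of stimulus presentation, per condition, with a bootstrap spread over
#' trials. A stationary population shows overlapping rates across
#' durations — firing rate at the end of the stimulus carries no duration
#' signal.
#'
#' @param rasters A list of `"spike_raster"`s (conditions).
#' @param window_ms Final window, ms (default 100).
#' @param n_boot Bootstrap resamples over trials.
#' @param rng_seed Seed.
#' @return A data frame: `T`, `light`, `rate_hz`, `boot_sd`.
#' @export
endwindow_rate <- function(rasters, window_ms = 100, n_boot = 200L,
                           rng_seed = 1L) {
  if (inherits(rasters, "spike_raster")) rasters <- list(rasters)
  seeds <- derive_seeds(rng_seed, length(rasters))
  rows <- lapply(seq_along(rasters), function(i) {
    r <- rasters[[i]]
    T <- r$condition$T
    if (T < window_ms)
      stop("stimulus duration ", T, " ms is shorter than the ", window_ms,
           " ms window")
    sel <- r$time_ms >= T - window_ms & r$time_ms < T
    per_trial <- 1000 * rowMeans(r$counts[, sel, drop = FALSE])
    boot <- withr_seed(seeds[i], vapply(seq_len(n_boot), function(b) {
      mean(sample(per_trial, length(per_trial), replace = TRUE))
    }, numeric(1L)))
    data.frame(T = T, light = isTRUE(r$condition$light),
               rate_hz = mean(per_trial), boot_sd = stats::sd(boot))
  })
  do.call(rbind, rows)
}

#' Summated spike count over the stimulus
#'
#' The count-code probe: spikes accumulated between response onset and
#' offset (default the full stimulus), per condition. Counts grow with
#' duration, and optogenetic excitation adds spikes at matched duration —
#' the signature that distinguishes an integration code from a stopwatch
#' code.
#'
#' @param rasters A list of `"spike_raster"`s.
#' @param onset_ms,offset_ms Integration window, ms; `offset_ms = NULL`
#'   uses each condition's stimulus duration.
#' @return A data frame: `T`, `light`, `mean_count`, `sd_count`.
#' @export
count_code <- function(rasters, onset_ms = 0, offset_ms = NULL) {
  if (inherits(rasters, "spike_raster")) rasters <- list(rasters)
  rows <- lapply(rasters, function(r) {
    off <- if (is.null(offset_ms)) r$condition$T else offset_ms
    if (!is.finite(onset_ms) || !is.finite(off) || onset_ms >= off)
      stop("invalid onset/offset window")
    sel <- r$time_ms >= onset_ms & r$time_ms < off
    counts <- rowSums(r$counts[, sel, drop = FALSE])
    data.frame(T = r$condition$T, light = isTRUE(r$condition$light),
               mean_count = mean(counts), sd_count = stats::sd(counts))
  })
  do.call(rbind, rows)
}

#' Time needed to accumulate a target spike count
#'
#' From a mean-rate profile (deterministic: the time at which the
#' cumulative expected count crosses the target, linearly interpolated) or
#' from a raster (stochastic: per-trial first crossing, averaged over the
#' trials that reach the target). Boosted drive reaches any target count
#' earlier, so light-on times fall below light-off times under
#' photoexcitation.
#'
#' @param x A numeric rate profile (spikes per 1-ms bin, population-summed)
#'   or a `"spike_raster"` / `"population_drive"` (its counts are used).
#' @param target_count Target accumulated spike count.
#' @return A list: `time_ms` (NA when unreachable, with `max_time_ms`
#'   reporting the trace end), `reached` (fraction of trials reaching the
#'   target, 1 for the deterministic route).
#' @export
time_to_count <- function(x, target_count) {
  stopifnot(target_count > 0)
  if (is.numeric(x)) {
    cum <- cumsum(x)
    if (cum[length(cum)] < target_count)
      return(list(time_ms = NA_real_, reached = 0,
                  max_time_ms = length(cum)))
    i <- which(cum >= target_count)[1L]
    prev <- if (i == 1L) 0 else cum[i - 1L]
    frac <- (target_count - prev) / (cum[i] - prev)
    return(list(time_ms = (i - 1L) + frac, reached = 1,
                max_time_ms = length(cum)))
  }
  counts <- x$counts
  t0 <- which(x$time_ms >= 0)
  counts <- counts[, t0, drop = FALSE]
  per_trial <- apply(counts, 1L, function(k) {
    cum <- cumsum(k)
    i <- which(cum >= target_count)[1L]
    if (is.na(i)) NA_real_ else i
  })
  reached <- mean(!is.na(per_trial))
  list(time_ms = if (reached > 0) mean(per_trial, na.rm = TRUE) else NA_real_,
       reached = reached, max_time_ms = ncol(counts))
}

#' Classify a neuron as intensity-coding
#'
#' A neuron codes intensity when the linear correlation between its
#' per-trial firing rate (whole-stimulus mean) and the stimulus intensity
#' is significant against the null distribution of correlations obtained by
#' shuffling the intensity labels (1000 shuffles, two-sided empirical p,
#' alpha 0.05).
#'
#' @param rates Per-trial firing rates (spikes/s or any monotone measure).
#' @param intensities Per-trial stimulus intensities (>= 2 distinct values
#'   with repeats).
#' @param n_shuffles Label shuffles for the null (default 1000).
#' @param alpha Significance level.
#' @param rng_seed Seed.
#' @return A list: `coding` (logical), `p_value`, `r` (observed Pearson
#'   correlation).
#' @export
classify_intensity_coding <- function(rates, intensities,
                                      n_shuffles = 1000L, alpha = 0.05,
                                      rng_seed = 1L) {
  if (length(unique(intensities)) < 2L)
    stop("need at least 2 intensity levels")
  if (length(rates) != length(intensities))
    stop("'rates' and 'intensities' must have equal length")
  r_obs <- suppressWarnings(stats::cor(rates, intensities))
  if (!is.finite(r_obs)) r_obs <- 0
  r_null <- withr_seed(rng_seed, vapply(seq_len(n_shuffles), function(i) {
    r <- suppressWarnings(stats::cor(rates, sample(intensities)))
    if (is.finite(r)) r else 0
  }, numeric(1L)))
  p <- (sum(abs(r_null) >= abs(r_obs)) + 1) / (n_shuffles + 1)
  list(coding = p < alpha, p_value = p, r = r_obs)
}

#' Resampled population statistics at a fixed coding fraction
#'
#' Resamples a pool of neurons so that each surrogate population contains
#' `coding_fraction` intensity-coding and `1 - coding_fraction` non-coding
#' neurons (with replacement; 90/10 by default), and records the population
#' mean rate per condition at each iteration — the clouds used to display
#' population intensity coding under the light conditions.
#'
#' @param neuron_rates Matrix (neurons x conditions) of mean rates.
#' @param coding Logical vector flagging the coding neurons.
#' @param coding_fraction Fraction of coding neurons per resample.
#' @param n_iter Resampling iterations.
#' @param n_sample Neurons per resample (default the pool size).
#' @param rng_seed Seed.
#' @return A matrix (`n_iter` x conditions) of population mean rates, with
#'   the sampled class counts in attributes `n_coding` / `n_noncoding`.
#' @export
resample_coding_population <- function(neuron_rates, coding,
                                       coding_fraction = 0.9,
                                       n_iter = 1000L, n_sample = NULL,
                                       rng_seed = 1L) {
  neuron_rates <- as.matrix(neuron_rates)
  if (length(coding) != nrow(neuron_rates))
    stop("'coding' must flag every row of 'neuron_rates'")
  if (!any(coding) || !any(!coding))
    stop("both coding and non-coding neurons must be present")
  if (is.null(n_sample)) n_sample <- nrow(neuron_rates)
  n_cod <- round(coding_fraction * n_sample)
  n_non <- n_sample - n_cod
  idx_cod <- which(coding); idx_non <- which(!coding)
  if (n_cod > length(idx_cod) || n_non > length(idx_non))
    warning("fewer neurons than requested in a class; sampling with replacement")
  out <- withr_seed(rng_seed, {
    t(vapply(seq_len(n_iter), function(i) {
      pick <- c(sample(idx_cod, n_cod, replace = TRUE),
                sample(idx_non, n_non, replace = TRUE))
      colMeans(neuron_rates[pick, , drop = FALSE])
    }, numeric(ncol(neuron_rates))))
  })
  colnames(out) <- colnames(neuron_rates)
  attr(out, "n_coding") <- n_cod
  attr(out, "n_noncoding") <- n_non
  out
}
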