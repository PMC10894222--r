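# A deterministic "raster" with a known rate step: one trial whose counts
# equal the expected rate (useful for exact smoothing/detection checks).
step_raster <- function(T = 694, t_pre = 500, rate_base = 0.002,
                        rate_stim = 0.06, n_trials = 200, seed = 1) {
  time_ms <- seq.int(-t_pre, T + 199)
  rate <- ifelse(time_ms >= 0 & time_ms < T, rate_stim, rate_base)
  counts <- withr::with_seed(seed, matrix(
    rpois(n_trials * length(time_ms), rep(rate, each = n_trials)),
    nrow = n_trials))
  structure(list(counts = counts, time_ms = time_ms, bin_width = 1,
                 rate = rate, condition = list(T = T, light = FALSE,
                                               intensity_gain = 1)),
            class = "spike_raster")
}

test_that("z-scored responses are centered in baseline and jump at onset", {
  r <- step_raster(T = 400, t_pre = 900, n_trials = 300)
  z <- zscore_response(r, baseline_window = c(-800, 0))
  expect_false(z$excluded)
  base <- z$z[z$time_ms >= -700 & z$time_ms < -100]
  expect_lt(abs(mean(base)), 2)
  stim <- z$z[z$time_ms > 50 & z$time_ms < 350]
  expect_gt(mean(stim), 10 * abs(mean(base)) + 5)
  # zero-variance baseline is flagged
  silent <- r
  silent$counts[] <- 0L
  expect_warning(zs <- zscore_response(silent), "zero baseline variance")
  expect_true(zs$excluded)
})

test_that("the half-Gaussian kernel is normalized and smoothing preserves a constant", {
  k <- vibratime:::half_gaussian_kernel(25)
  expect_equal(sum(k), 1, tolerance = 1e-6)
  flat <- structure(list(counts = matrix(5L, 3, 600),
                         time_ms = seq.int(-100, 499), bin_width = 1,
                         condition = list(T = 400, light = FALSE)),
                    class = "spike_raster")
  ps <- population_psth(flat, smoothing_sigma = 25)
  expect_equal(ps$rate, rep(5000, 600), tolerance = 1e-6)
})

test_that("boundary-aware smoothing leaks no response mass across boundaries", {
  # deterministic step at t = 0: pre-onset smoothed mass must stay at baseline
  time_ms <- seq.int(-300, 399)
  counts <- matrix(ifelse(time_ms >= 0, 60L, 0L), 1, length(time_ms),
                   byrow = TRUE)
  r <- structure(list(counts = counts, time_ms = time_ms, bin_width = 1,
                      condition = list(T = 400, light = FALSE)),
                 class = "spike_raster")
  ps <- population_psth(r, smoothing_sigma = 25, flip_ms = 200)
  expect_true(all(ps$rate[ps$time_ms < 0] == 0))
  # and a step down at the flip boundary leaks nothing forward
  counts2 <- matrix(ifelse(time_ms < 200, 60L, 0L), 1, length(time_ms))
  r2 <- structure(list(counts = counts2, time_ms = time_ms, bin_width = 1,
                       condition = list(T = 400, light = FALSE)),
                  class = "spike_raster")
  ps2 <- population_psth(r2, smoothing_sigma = 25, flip_ms = 200)
  expect_true(all(ps2$rate[ps2$time_ms >= 200] == 0))
})

test_that("edge pooling returns the first 150 and final 50 ms", {
  r <- step_raster(T = 694)
  ps <- population_psth(r, pool_edges = TRUE)
  expect_length(ps$time_ms, 200L)
  expect_true(all(ps$time_ms < 150 | ps$time_ms >= 694 - 50))
})

test_that("onset/offset detection finds a clean step within tolerance", {
  r <- step_raster(T = 694, rate_stim = 0.08, n_trials = 400)
  ps <- population_psth(r, flip_ms = 347)
  oo <- detect_onset_offset(ps, stim_T = 694)
  expect_true(oo$valid_onset && oo$valid_offset)
  expect_lt(abs(oo$onset_ms - 0), 10)
  expect_lt(abs(oo$offset_ms - 694), 10)
  # flat trace: no crossings
  flat <- list(time_ms = seq.int(-500, 500),
               rate = rep(3, 1001))
  oo2 <- detect_onset_offset(flat)
  expect_false(oo2$valid_onset || oo2$valid_offset)
})

test_that("uniform rate boosts leave boundaries fixed but raise counts", {
  # the stopwatch-vs-integration dissociation: photoexcitation must not move
  # detected onset/offset while the onset-to-offset spike count grows
  r_off <- step_raster(T = 694, rate_stim = 0.06, n_trials = 400, seed = 2)
  r_on <- step_raster(T = 694, rate_stim = 0.09, n_trials = 400, seed = 3)
  oo_off <- detect_onset_offset(population_psth(r_off, flip_ms = 347),
                                stim_T = 694)
  oo_on <- detect_onset_offset(population_psth(r_on, flip_ms = 347),
                               stim_T = 694)
  expect_lt(abs(oo_on$onset_ms - oo_off$onset_ms), 10)
  expect_lt(abs(oo_on$offset_ms - oo_off$offset_ms), 10)
  cc <- count_code(list(r_off, r_on))
  expect_gt(cc$mean_count[2], cc$mean_count[1])
})

test_that("end-window rates overlap across durations for a stationary code", {
  pop <- fixture_population(10)
  conds <- data.frame(T = c(334, 427, 544, 694), light = FALSE)
  rs <- make_raster_set(pop, conds, n_trials = 150, rng_seed = 6)
  ew <- endwindow_rate(rs, window_ms = 100, rng_seed = 2)
  spread <- diff(range(ew$rate_hz))
  expect_lt(spread, 8 * max(ew$boot_sd))
  # photoexcitation shifts every duration upward
  conds_on <- conds; conds_on$light <- TRUE
  rs_on <- make_raster_set(pop, rbind(conds, conds_on), n_trials = 150,
                           rng_seed = 7)
  ew_all <- endwindow_rate(rs_on, window_ms = 100, rng_seed = 3)
  expect_true(all(ew_all$rate_hz[ew_all$light] >
                    ew_all$rate_hz[!ew_all$light]))
  expect_error(endwindow_rate(list(rs[[1]]), window_ms = 1000), "shorter")
})

test_that("summated counts are ordered by duration and boosted by light", {
  pop <- fixture_population(10)
  conds <- data.frame(T = c(161, 334, 694), light = FALSE)
  rs <- make_raster_set(pop, conds, n_trials = 100, rng_seed = 8)
  cc <- count_code(rs)
  expect_true(all(diff(cc$mean_count) > 0))
  conds2 <- data.frame(T = c(334, 334), light = c(FALSE, TRUE))
  rs2 <- make_raster_set(pop, conds2, n_trials = 100, rng_seed = 9)
  cc2 <- count_code(rs2)
  expect_gt(cc2$mean_count[2], cc2$mean_count[1])
})

test_that("time to a target count follows rate x time and halves when rate doubles", {
  # constant population-summed rate of 50 spikes/s = 0.05 spikes/ms
  profile <- rep(0.05, 1000)
  expect_equal(time_to_count(profile, 20)$time_ms, 400, tolerance = 0.5)
  expect_equal(time_to_count(2 * profile, 20)$time_ms, 200, tolerance = 0.5)
  # expected count over 334 ms at 50 spikes/s is 16.7
  expect_equal(sum(rep(0.05, 334)), 16.7, tolerance = 1e-9)
  # unreachable target reports the trace end
  out <- time_to_count(rep(0.01, 100), 20)
  expect_true(is.na(out$time_ms))
  expect_equal(out$max_time_ms, 100)
})

test_that("stochastic time-to-count matches the deterministic value", {
  rate <- rep(0.05, 1000)
  counts <- withr::with_seed(4, matrix(rpois(1e4 * 1000, 0.05), nrow = 1e4))
  r <- structure(list(counts = counts, time_ms = 0:999, bin_width = 1,
                      condition = list(T = 1000, light = FALSE)),
                 class = "spike_raster")
  st <- time_to_count(r, 20)
  det <- time_to_count(rate, 20)$time_ms
  # per-trial first-crossing times: SE of the mean ~ sd/sqrt(n)
  expect_lt(abs(st$time_ms - det), 5)
  expect_equal(st$reached, 1)
  # boosted drive reaches the target earlier
  r_on <- structure(list(counts = counts + withr::with_seed(5,
                    matrix(rpois(1e4 * 1000, 0.02), nrow = 1e4)),
                    time_ms = 0:999, bin_width = 1,
                    condition = list(T = 1000, light = TRUE)),
                    class = "spike_raster")
  expect_lt(time_to_count(r_on, 20)$time_ms, st$time_ms)
})

test_that("intensity-coding classification separates coding from non-coding", {
  set.seed(6)
  I <- rep(c(34, 52, 64, 78, 119), each = 30)
  coding_rates <- 10 + 0.2 * I + rnorm(length(I), 0, 2)
  res <- classify_intensity_coding(coding_rates, I, n_shuffles = 1000,
                                   rng_seed = 1)
  expect_true(res$coding)
  expect_lt(res$p_value, 0.01)
  # calibration: an intensity-independent neuron is rarely called coding
  calls <- vapply(1:40, function(i) {
    rates <- withr::with_seed(100 + i, rnorm(length(I), 20, 3))
    classify_intensity_coding(rates, I, n_shuffles = 200,
                              rng_seed = i)$coding
  }, logical(1L))
  expect_gte(mean(!calls), 0.85)
})

test_that("90/10 coding resampling yields stable cloud means", {
  set.seed(8)
  n <- 40L
  rates <- cbind(low = rnorm(n, 15, 3), high = rnorm(n, 22, 3))
  coding <- rep(c(TRUE, FALSE), c(30, 10))
  # 36 coding draws are requested from 30 coding neurons: warned, then
  # satisfied by sampling with replacement
  expect_warning(
    r1 <- resample_coding_population(rates, coding, n_iter = 500,
                                     rng_seed = 1),
    "with replacement")
  expect_warning(
    r2 <- resample_coding_population(rates, coding, n_iter = 500,
                                     rng_seed = 2),
    "with replacement")
  expect_equal(attr(r1, "n_coding"), 36)
  expect_lt(max(abs(colMeans(r1) - colMeans(r2))), 0.5)
  expect_error(resample_coding_population(rates, rep(TRUE, n)),
               "non-coding")
})
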