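test_that("the stimulus window gates with ~1 ms logistic shoulders", {
  expect_equal(window_W(167, T = 334, t0 = 0), 1, tolerance = 1e-10)
  expect_equal(window_W(0, T = 334, t0 = 0), 0.5, tolerance = 1e-10)
  expect_lt(window_W(-20, T = 334, t0 = 0), 1e-8)
  # closing gate mirrors the opening one
  expect_equal(window_W(334, T = 334, t0 = 0), 0.5, tolerance = 1e-10)
})

test_that("mechanoreceptor current decays from peak to steady state", {
  p <- fixture_neuron()
  # at one time constant past onset the bracket has decayed by 1/e
  t <- p$t0_M + p$tau_M
  bracket <- mechano_current(t, p, T = 500) / window_W(t, 500, p$t0_M)
  expect_equal(bracket, p$I1_ss + (p$I1_peak - p$I1_ss) / exp(1),
               tolerance = 1e-10)
  expect_lt(abs(mechano_current(500 + 200, p, T = 500)), 1e-8)
})

test_that("optogenetic current includes the post-light-offset term", {
  p <- fixture_neuron()
  off <- neuron_params()   # all currents zero
  expect_equal(opto_current(0:600, off, T = 500), rep(0, 601))
  T <- 500
  t <- T + p$t0_O + p$tau_I
  expected_post <- p$I3_peak * exp(-1) * (1 / (1 + exp(-p$tau_I)))
  gated <- (p$I2_ss + (p$I2_peak - p$I2_ss) *
              exp(-(t - p$t0_O) / p$tau_O)) * window_W(t, T, p$t0_O)
  expect_equal(opto_current(t, p, T), gated + expected_post,
               tolerance = 1e-12)
  # mid-stimulus, far past the onset transient: ~ I2_ss
  mid <- p$t0_O + 8 * p$tau_O
  expect_equal(opto_current(mid, p, T = 500) /
                 window_W(mid, 500, p$t0_O), p$I2_ss, tolerance = 1e-3)
})

test_that("the I/F curve has the stated floor, ceiling and midpoint", {
  p <- neuron_params(lambda_max = 0.08, upsilon = 1)
  expect_equal(rate_from_current(-100, p), 1e-4, tolerance = 1e-12)
  expect_equal(rate_from_current(100, p), 0.08 + 1e-4, tolerance = 1e-12)
  expect_equal(rate_from_current(0, p), 0.04 + 1e-4, tolerance = 1e-12)
})

test_that("rate is monotone non-decreasing in current for any (lambda, upsilon)", {
  set.seed(3)
  I <- seq(-2, 2, length.out = 201)
  for (i in 1:20) {
    p <- neuron_params(lambda_max = runif(1, 0.001, 0.5),
                       upsilon = runif(1, 0.05, 10))
    expect_true(all(diff(rate_from_current(I, p)) >= 0))
  }
})

test_that("simulated spikes are Poisson with the model rate", {
  p <- fixture_neuron()
  r <- simulate_spikes(p, T = 60, n_trials = 1e4, rng_seed = 9)
  rate <- r$rate
  m <- colMeans(r$counts)
  v <- apply(r$counts, 2L, var)
  n <- nrow(r$counts)
  se <- sqrt(rate / n)
  z <- abs(m - rate) / se
  # 3-SE agreement per bin, allowing the expected multiple-comparison tail
  expect_gte(mean(z <= 3), 0.95)
  expect_true(all(z <= 4.5))
  # variance equals mean within its Poisson sampling spread
  se_var <- sqrt(rate / n + 2 * rate^2 / (n - 1))
  expect_true(all(abs(v - rate) <= 4.5 * se_var))
  # determinism
  r2 <- simulate_spikes(p, T = 60, n_trials = 5, rng_seed = 9)
  r3 <- simulate_spikes(p, T = 60, n_trials = 5, rng_seed = 9)
  expect_identical(r2$counts, r3$counts)
})

test_that("zeroed currents with tiny lambda give a near-silent raster", {
  p <- neuron_params(I0 = -5, lambda_max = 1e-3)
  r <- simulate_spikes(p, T = 200, n_trials = 100, rng_seed = 1)
  expect_lt(mean(r$counts), 5e-4)
})

test_that("photoexcitation boosts the rate but conserves the temporal profile", {
  p <- fixture_neuron()
  t <- 0:499
  off <- lnp_rate(p, t, T = 500, light = FALSE)
  on <- lnp_rate(p, t, T = 500, light = TRUE)
  inside <- t > 5 & t < 495
  expect_true(all(on[inside] > off[inside]))
  expect_equal(which.max(on), which.max(off), tolerance = 3)
})

test_that("binned PSTHs integrate the raster", {
  p <- fixture_neuron()
  r <- simulate_spikes(p, T = 100, n_trials = 20, t_pre = 50, rng_seed = 2)
  ps <- bin_psth(r, 10)
  expect_equal(sum(ps$counts), sum(r$counts))
  expect_equal(ps$bin_width, 10)
  expect_equal(ps$n_trials, 20L)
})

test_that("LNP fit attributes no stimulus current to a flat PSTH", {
  p0 <- neuron_params(I0 = -0.3, lambda_max = 0.08)   # baseline only
  r <- simulate_spikes(p0, T = 400, n_trials = 150, t_pre = 300,
                       rng_seed = 4)
  fit <- fit_lnp(list(bin_psth(r)), n_starts = 3L, rng_seed = 5)
  profile <- predict(fit, t = 0:399, T = 400)
  base <- rate_from_current(fit$params$I0, fit$params)
  # fitted in-stimulus rate stays within 2 spikes/s of the fitted baseline
  expect_lt(1000 * max(abs(profile - base)), 2)
})

test_that("identical light-on and light-off PSTHs imply null opto currents", {
  p <- neuron_params(I0 = -0.3, I1_ss = 0.2, I1_peak = 0.45,
                     lambda_max = 0.08)
  r <- simulate_spikes(p, T = 400, n_trials = 200, t_pre = 200,
                       rng_seed = 6)
  ps_off <- bin_psth(r)
  ps_on <- ps_off
  ps_on$light <- TRUE
  fit <- fit_lnp(list(ps_off, ps_on), n_starts = 3L, rng_seed = 7)
  t <- 0:399
  with_opto <- lnp_rate(fit$params, t, T = 400, light = TRUE)
  without <- lnp_rate(fit$params, t, T = 400, light = FALSE)
  expect_lt(max(abs(with_opto - without)) / max(without), 0.15)
})

test_that("raster CSV and parameter JSON round-trip", {
  p <- fixture_neuron()
  r <- simulate_spikes(p, T = 80, n_trials = 10, t_pre = 20, rng_seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_raster_csv(r, path)
  r2 <- read_raster_csv(path)
  expect_equal(r2$counts, r$counts, ignore_attr = TRUE)
  expect_equal(r2$time_ms, r$time_ms)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_neuron_json(list(u1 = p), jpath)
  p2 <- read_neuron_json(jpath)$u1
  expect_equal(unlist(p2), unlist(p), tolerance = 1e-12)
})

test_that("spike_times expands counts into event lists", {
  r <- simulate_spikes(fixture_neuron(), T = 50, n_trials = 4, rng_seed = 3)
  st <- spike_times(r)
  expect_length(st, 4L)
  expect_equal(lengths(st), unname(rowSums(r$counts)))
  expect_true(all(unlist(st) >= 0))
})
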