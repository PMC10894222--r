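test_that("closed-form percept moments reduce correctly in limiting cases", {
  # zero drive, zero start: background-only variance
  pp <- percept_params(tau = 400, mu_b = 0, sigma2_b = 2)
  d <- integrate_percept(rep(0, 300), pp)
  expect_equal(d$mean, 0, tolerance = 1e-12)
  expect_equal(d$variance, 2 * (1 - exp(-2 * 300 / 400)), tolerance = 1e-12)
  # infinite time constant: pure accumulation of the drive
  pp2 <- percept_params(tau = 1e9)
  d2 <- integrate_percept(rep(0.5, 400), pp2)
  expect_equal(d2$mean, 0.5 * 400, tolerance = 1e-3)
  # T >> tau: steady state mu_b + f * tau
  pp3 <- percept_params(tau = 50, mu_b = 1.5)
  d3 <- integrate_percept(rep(0.8, 2000), pp3)
  expect_equal(d3$mean, 1.5 + 0.8 * 50, tolerance = 0.01)
})

test_that("perceived duration grows with actual duration under constant drive", {
  pp <- percept_params(tau = 500, sigma2_b = 1)
  means <- vapply(c(161, 262, 334, 427, 544, 694), function(T)
    integrate_percept(rep(2, T), pp)$mean, numeric(1L))
  expect_true(all(diff(means) > 0))
})

test_that("closed form agrees with Euler Monte-Carlo simulation", {
  pp <- percept_params(tau = 350, mu_b = 4, sigma2_b = 3)
  # a non-trivial drive profile: onset transient decaying to steady state
  f <- 1.5 * (1 + 1.5 * exp(-(0:299) / 48))
  cl <- integrate_percept(f, pp)
  y <- simulate_percept(f, pp, n_trials = 1e4, rng_seed = 12)
  se_mean <- sd(y) / sqrt(length(y))
  se_var <- var(y) * sqrt(2 / (length(y) - 1))
  expect_lt(abs(mean(y) - cl$mean), 3 * se_mean)
  expect_lt(abs(var(y) - cl$variance), 3 * se_var)
})

test_that("choice probability follows the lapse-aware erf rule", {
  pp <- percept_params(p_L = 0)
  a <- structure(list(mean = 10, variance = 4, duration_T = 300),
                 class = "percept_distribution")
  b <- structure(list(mean = 10, variance = 4, duration_T = 300),
                 class = "percept_distribution")
  expect_equal(choice_probability(a, b, pp), 0.5, tolerance = 1e-12)
  # full lapse: bias alone decides
  pl <- percept_params(p_L = 1, b_L = 0.73)
  expect_equal(choice_probability(a, b, pl), 0.73, tolerance = 1e-12)
  # swapping the stimuli complements the probability
  c2 <- structure(list(mean = 14, variance = 3, duration_T = 400),
                  class = "percept_distribution")
  expect_equal(choice_probability(a, c2, pp) + choice_probability(c2, a, pp),
               1, tolerance = 1e-12)
  # degenerate comparison rejected
  z <- structure(list(mean = 1, variance = 0, duration_T = 100),
                 class = "percept_distribution")
  expect_error(choice_probability(z, z, pp), "degenerate")
})

test_that("choice probabilities stay in [0, 1] for extreme percepts", {
  pp <- percept_params(p_L = 0.1, b_L = 0.2)
  big <- structure(list(mean = 1e6, variance = 1, duration_T = 1),
                   class = "percept_distribution")
  small <- structure(list(mean = -1e6, variance = 1, duration_T = 1),
                     class = "percept_distribution")
  p1 <- choice_probability(small, big, pp)
  p2 <- choice_probability(big, small, pp)
  expect_true(p1 >= 0 && p1 <= 1 && p2 >= 0 && p2 <= 1)
})

test_that("a drive boost on stimulus 2 raises the choice probability", {
  pp <- percept_params(tau = 500)
  p1 <- integrate_percept(rep(2, 334), pp)
  p2 <- integrate_percept(rep(2, 334), pp)
  p2b <- integrate_percept(rep(2.6, 334), pp)
  expect_gt(choice_probability(p1, p2b, pp),
            choice_probability(p1, p2, pp))
})

test_that("curve_pse interpolates the 50% crossing", {
  expect_equal(curve_pse(c(-1, 0, 1), c(0.2, 0.5, 0.9)), 0)
  expect_equal(curve_pse(c(-1, 1), c(0.4, 0.6)), 0, tolerance = 1e-12)
  expect_true(is.na(curve_pse(c(-1, 1), c(0.6, 0.9))))
})
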