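test_that("a single-Gaussian sample concentrates weight in one class", {
  set.seed(2)
  n <- 50L
  mu <- c(-0.5, 0.3, 1.2, 0.1, 0.4, -0.2, 0.1, 1)
  X <- matrix(rnorm(n * 8, 0, 0.05), n, 8)
  X <- sweep(X, 2L, mu, "+")
  colnames(X) <- c("I0", "I1_ss", "I1_peak", "I2_ss", "I2_peak", "I3_peak",
                   "lambda_max", "upsilon")
  fit <- fit_neuron_mixture(X, G = 5, rng_seed = 3)
  top <- which.max(fit$weights)
  expect_gte(fit$weights[top], 0.95)
  # relative 10% on the sizeable parameters, absolute floor on the small ones
  expect_true(all(abs(fit$means[top, ] - mu) <
                    pmax(0.10 * abs(mu), 0.03)))
})

test_that("two separated clusters are recovered with high assignment accuracy", {
  fx <- fixture_two_clusters()
  fit <- fit_neuron_mixture(fx$X, G = 5, rng_seed = 1)
  acc <- vibratime:::cluster_accuracy(fx$labels, fit$assignments)
  expect_gte(acc, 0.95)
  expect_gte(sum(sort(fit$weights, decreasing = TRUE)[1:2]), 0.9)
})

test_that("mixture assignments agree with an independent EM clustering", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  fx <- fixture_two_clusters()
  em <- Mclust(fx$X, G = 2, verbose = FALSE)
  fit <- fit_neuron_mixture(fx$X, G = 5, rng_seed = 1)
  agree <- vibratime:::cluster_accuracy(em$classification, fit$assignments)
  expect_gte(agree, 0.95)
})

test_that("too few vectors for the requested G is an informative error", {
  X <- matrix(rnorm(4 * 8), 4, 8)
  colnames(X) <- c("I0", "I1_ss", "I1_peak", "I2_ss", "I2_peak", "I3_peak",
                   "lambda_max", "upsilon")
  expect_error(fit_neuron_mixture(X, G = 5), "smaller G")
})

test_that("population sampling is reproducible and respects positivity", {
  fx <- fixture_two_clusters()
  fit <- fit_neuron_mixture(fx$X, G = 5, rng_seed = 1)
  pop1 <- sample_population(fit, n = 200, rng_seed = 10)
  pop2 <- sample_population(fit, n = 200, rng_seed = 10)
  expect_identical(unlist(pop1[[37]]), unlist(pop2[[37]]))
  lam <- vapply(pop1, `[[`, numeric(1L), "lambda_max")
  ups <- vapply(pop1, `[[`, numeric(1L), "upsilon")
  expect_true(all(lam > 0) && all(ups > 0))
  expect_true(is.integer(attr(pop1, "n_rejected")))
  # fixed taus attached
  expect_equal(pop1[[1]]$tau_M, 48)
})

test_that("sampled parameter grand mean approaches the mixture mean", {
  fx <- fixture_two_clusters()
  fit <- fit_neuron_mixture(fx$X, G = 5, rng_seed = 1)
  pop <- sample_population(fit, n = 20000, rng_seed = 2)
  sampled <- colMeans(do.call(rbind, lapply(pop, function(p)
    unlist(p[c("I0", "I1_ss", "I1_peak", "I2_ss", "I2_peak", "I3_peak",
               "lambda_max", "upsilon")]))))
  target <- drop(fit$weights %*% fit$means)
  # rejection sampling trims the negative lambda/upsilon tails slightly
  expect_true(all(abs(sampled - target) < 0.05))
})

test_that("population drive matches the summed rate and superposes", {
  pop <- fixture_population(10)
  rate <- population_rate(pop, T = 100)
  drv <- population_drive(pop, T = 100, n_trials = 1000, rng_seed = 5)
  se <- sqrt(rate / 1000)
  expect_true(all(abs(colMeans(drv$counts) - rate) <= 3 * se))
  # superposition of two sub-populations
  r1 <- population_rate(pop[1:4], T = 100)
  r2 <- population_rate(pop[5:10], T = 100)
  expect_equal(r1 + r2, rate, tolerance = 1e-12)
  # doubling the population doubles the expected drive
  expect_equal(population_rate(c(pop, pop), T = 100), 2 * rate,
               tolerance = 1e-12)
})

test_that("photoexcitation never decreases the expected drive", {
  pop <- fixture_population(10)
  off <- population_rate(pop, T = 200, light = FALSE)
  on <- population_rate(pop, T = 200, light = TRUE)
  inside <- seq(10, 190)
  expect_true(all(on[inside] >= off[inside]))
})

test_that("mixture JSON round-trips", {
  fx <- fixture_two_clusters()
  fit <- fit_neuron_mixture(fx$X, G = 3, rng_seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_mixture_json(fit, path)
  fit2 <- read_mixture_json(path)
  expect_equal(fit2$weights, fit$weights, tolerance = 1e-9)
  expect_equal(fit2$means, fit$means, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit2$covariances[, , 2], fit$covariances[, , 2],
               tolerance = 1e-9, ignore_attr = TRUE)
  pop <- sample_population(fit2, n = 5, rng_seed = 1)
  expect_length(pop, 5L)
})
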