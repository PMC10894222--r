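sim_choice_table <- function(gen = c(gamma = 0.05, lambda_u = 0.05, u = 0,
                                     nu = 0.1),
                             n = 500L, seed = 1L,
                             levels = seq(-0.35, 0.35, length.out = 7),
                             shift = 0) {
  p <- vibratime:::psychometric_curve(levels - shift, gen["gamma"],
                                      gen["lambda_u"], gen["u"], gen["nu"])
  k <- withr::with_seed(seed, rbinom(length(levels), n, p))
  choice_table(delta_T = levels, delta_I = 0, n_trials = n, n_chose2 = k)
}

test_that("symmetric data yield a PSE at zero and translation shifts it", {
  tb <- sim_choice_table(seed = 2)
  fit <- fit_psychometric(tb, "duration")
  expect_lt(abs(fit$pse), 0.03)
  # shifting the generating curve by delta shifts the PSE by delta
  tb_s <- sim_choice_table(seed = 2, shift = 0.08)
  fit_s <- fit_psychometric(tb_s, "duration")
  expect_equal(fit_s$pse - fit$pse, 0.08, tolerance = 0.03)
  # slope essentially unchanged by the translation
  expect_equal(fit_s$slope, fit$slope, tolerance = 0.25)
})

test_that("fitted curves are monotone and bounded by the asymptotes", {
  tb <- sim_choice_table(seed = 3)
  fit <- fit_psychometric(tb, "duration")
  grid <- seq(-0.6, 0.6, length.out = 300)
  pr <- predict(fit, grid)
  expect_true(all(diff(pr) >= 0))
  expect_true(all(pr >= fit$par["gamma"] - 1e-9))
  expect_true(all(pr <= 1 - fit$par["lambda_u"] + 1e-9))
})

test_that("degenerate all-zero choice data are flagged", {
  tb <- choice_table(delta_T = seq(-0.35, 0.35, length.out = 7),
                     delta_I = 0, n_trials = 100, n_chose2 = rep(0, 7))
  expect_warning(fit <- fit_psychometric(tb, "duration"), "degenerate")
  expect_true(fit$degenerate)
})

test_that("bias is flat without coupling and zero at the irrelevant zero level", {
  obs <- synthetic_observer(coupling = 0)
  design <- build_trial_matrix("duration")
  beh <- make_behavior_session(obs, design, n_trials_per_cell = 400,
                               rng_seed = 11)
  b <- bias_measure(beh, "duration")
  expect_equal(b$bias_percent[abs(b$delta) < 1e-9], 0)
  expect_true(all(abs(b$bias_percent) < 5))
})

test_that("positive intensity-duration coupling produces a monotone bias", {
  obs <- synthetic_observer(coupling = 1)
  design <- build_trial_matrix("duration")
  beh <- make_behavior_session(obs, design, n_trials_per_cell = 400,
                               rng_seed = 12)
  b <- bias_measure(beh, "duration")
  fitline <- lm(bias_percent ~ delta, data = b)
  expect_gt(coef(fitline)["delta"], 0)
  expect_gt(cor(b$delta, b$bias_percent), 0.9)
})

test_that("the resampling bias test is calibrated and detects real shifts", {
  # a large injected bias is detected at the resolution of the iteration count
  obs <- synthetic_observer()
  design <- build_trial_matrix("duration")
  A <- make_behavior_session(obs, design, 200, rng_seed = 21)
  B <- A
  B$n_chose2 <- pmin(B$n_trials, B$n_chose2 +
                       round(0.25 * B$n_trials))   # B well above A
  res <- permutation_bias_test(A, B, "duration", n_iter = 1000,
                               rng_seed = 3)
  expect_lte(res$p_value, 0.001)
  # same-generator conditions: null p spread over (0, 1), rejecting rarely
  reps <- 60L
  seeds <- withr::with_seed(7, sample.int(1e6, 2 * reps))
  pvals <- vapply(seq_len(reps), function(i) {
    A0 <- make_behavior_session(obs, design, 100,
                                rng_seed = seeds[2 * i - 1])
    B0 <- make_behavior_session(obs, design, 100, rng_seed = seeds[2 * i])
    permutation_bias_test(A0, B0, "duration", n_iter = 200,
                          rng_seed = i)$p_value
  }, numeric(1L))
  expect_lte(mean(pvals <= 0.05), 0.15)
  expect_gt(mean(pvals), 0.3)
})

test_that("SVM separation reads chance for identical clouds and zero for split ones", {
  set.seed(5)
  A <- cbind(rnorm(60), rnorm(60))
  B <- cbind(rnorm(60), rnorm(60))
  same <- svm_separation(A, B, rng_seed = 2)
  expect_gt(same$error, 0.3)
  far <- svm_separation(A, B + 12, rng_seed = 2)
  expect_lt(far$error, 0.05)
  # error decreases with separation distance
  mid <- svm_separation(A, B + 1.5, rng_seed = 2)
  expect_lt(far$error, mid$error + 1e-9)
  expect_lt(mid$error, same$error)
  expect_error(svm_separation(A[1:5, ], B), "20 points")
})

test_that("bootstrap psychometric clouds separate under an optogenetic-like shift", {
  tb0 <- sim_choice_table(n = 300, seed = 8)
  tb1 <- sim_choice_table(n = 300, seed = 9, shift = -0.12)  # leftward PSE
  boot0 <- bootstrap_psychometric(tb0, "duration", n_boot = 40,
                                  rng_seed = 1)
  boot1 <- bootstrap_psychometric(tb1, "duration", n_boot = 40,
                                  rng_seed = 2)
  sep <- svm_separation(boot0[, c("pse", "mean_choice")],
                        boot1[, c("pse", "mean_choice")], rng_seed = 3)
  expect_lt(sep$error, 0.1)
})

test_that("congruent trials are judged more accurately under intensity coupling", {
  obs <- synthetic_observer(coupling = 1)
  design <- build_trial_matrix("duration")
  beh <- make_behavior_session(obs, design, n_trials_per_cell = 300,
                               rng_seed = 31)
  res <- congruence_accuracy(beh, "duration", n_boot = 400, rng_seed = 4)
  expect_gt(res$accuracy["congruent"], res$accuracy["incongruent"])
  expect_lt(res$p_value, 0.05)
  # without coupling the two classes match within noise
  beh0 <- make_behavior_session(synthetic_observer(coupling = 0), design,
                                n_trials_per_cell = 300, rng_seed = 32)
  res0 <- congruence_accuracy(beh0, "duration", n_boot = 400, rng_seed = 5)
  expect_lt(abs(res0$accuracy["congruent"] - res0$accuracy["incongruent"]),
            3)
})

test_that("choice tables round-trip through CSV in both layouts", {
  tb <- sim_choice_table(n = 40, seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_choice_csv(tb, path)
  tb2 <- read_choice_csv(path)
  expect_equal(tb2$n_chose2, tb$n_chose2)
  expect_equal(tb2$delta_T, tb$delta_T)
  # long per-trial layout
  long <- do.call(rbind, lapply(seq_len(nrow(tb)), function(i) {
    data.frame(delta_T = tb$delta_T[i], delta_I = tb$delta_I[i],
               light = tb$light[i],
               chose2 = rep(c(1L, 0L), c(tb$n_chose2[i],
                                         tb$n_trials[i] - tb$n_chose2[i])))
  }))
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(long, path2, row.names = FALSE)
  tb3 <- read_choice_csv(path2)
  agg <- tb3[order(tb3$delta_T), ]
  expect_equal(agg$n_chose2, tb$n_chose2[order(tb$delta_T)])
})
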