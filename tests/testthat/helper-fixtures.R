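# Shared fixtures: small ground-truth objects used across test files.

# A neuron whose operating range sits on the sensitive part of the I/F
# sigmoid (all currents identifiable from moderate data).
fixture_neuron <- function() {
  neuron_params(I0 = -0.3, I1_ss = 0.2, I1_peak = 0.45,
                I2_ss = 0.15, I2_peak = 0.3, I3_peak = -0.25,
                lambda_max = 0.08, upsilon = 1)
}

# A small homogeneous population around the fixture neuron.
fixture_population <- function(n = 20L, seed = 1L, sd_frac = 0.1) {
  base <- unlist(fixture_neuron()[c("I0", "I1_ss", "I1_peak", "I2_ss",
                                    "I2_peak", "I3_peak", "lambda_max",
                                    "upsilon")])
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a <- base + stats::rnorm(8, 0, pmax(abs(base) * sd_frac, 0.01))
    a["lambda_max"] <- max(a["lambda_max"], 1e-3)
    a["upsilon"] <- max(a["upsilon"], 0.1)
    do.call(neuron_params, as.list(a))
  })
}

# Two well-separated clusters in the 8-parameter mixture space.
fixture_two_clusters <- function(n_per = 30L, seed = 4L) {
  centers <- rbind(c(-0.5, 0.3, 1.2, 0, 0, 0, 0.12, 1),
                   c(0.5, 1.2, 2.5, 0.5, 1, -0.3, 0.25, 2))
  set.seed(seed)
  lab <- rep(1:2, each = n_per)
  X <- centers[lab, ] + matrix(stats::rnorm(2 * n_per * 8, 0, 0.08),
                               2 * n_per, 8)
  colnames(X) <- c("I0", "I1_ss", "I1_peak", "I2_ss", "I2_peak", "I3_peak",
                   "lambda_max", "upsilon")
  list(X = X, labels = lab)
}
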