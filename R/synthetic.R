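#' Ground-truth synthetic observer
#'
#' The generating model for synthetic behavioral sessions: a leaky-
#' integrator percept observer driven by a constant population rate during
#' each stimulus, with an optional intensity-to-drive coupling (vibration
#' intensity scales the drive by `1 + coupling * (I/reference_I - 1)`, the
#' mechanism by which an irrelevant intensity difference biases perceived
#' duration and makes congruent trials easier than incongruent ones).
#'
#' Defaults are the desk-scale study conditions: tau = 500 ms, a 10%
#' lapse rate with unbiased lapses, and a summed drive of 2 spikes/ms
#' (a few hundred low-rate cortical units).
#'
#' @param percept A [percept_params()] object.
#' @param coupling Intensity-to-drive coupling coefficient (0 = the
#'   duration-only observer).
#' @param base_rate Summed population drive during the stimulus, spikes/ms.
#' @param reference_I Reference intensity, mm/s.
#' @param light_boost Multiplier on the drive of a photoexcited stimulus
#'   (1 = no optogenetic effect).
#' @return An object of class `"synthetic_observer"`.
#' @export
synthetic_observer <- function(percept = percept_params(tau = 500, mu_b = 0,
                                                        sigma2_b = 0,
                                                        p_L = 0.1, b_L = 0.5),
                               coupling = 0, base_rate = 2,
                               reference_I = 64, light_boost = 1.3) {
  stopifnot(inherits(percept, "percept_params"), base_rate > 0,
            light_boost > 0)
  structure(list(percept = percept, coupling = coupling,
                 base_rate = base_rate, reference_I = reference_I,
                 light_boost = light_boost),
            class = "synthetic_observer")
}

#' @export
print.synthetic_observer <- function(x, ...) {
  cat(sprintf(
    "Synthetic observer: drive %.2f spikes/ms, coupling %.2f (ref %g mm/s)\n",
    x$base_rate, x$coupling, x$reference_I))
  print(x$percept)
  invisible(x)
}

# Closed-form choice probability of the observer for one design row.
observer_choice_prob <- function(observer, T1, T2, I1, I2, light = "none") {
  g <- function(I) 1 + observer$coupling * (I / observer$reference_I - 1)
  b1 <- if (light == "excite_stim1") observer$light_boost else 1
  b2 <- if (light %in% c("excite_stim2", "inhibit_stim2"))
    observer$light_boost else 1
  p1 <- integrate_percept(rep(observer$base_rate * g(I1) * b1, T1),
                          observer$percept, T = T1)
  p2 <- integrate_percept(rep(observer$base_rate * g(I2) * b2, T2),
                          observer$percept, T = T2)
  choice_probability(p1, p2, observer$percept)
}

#' Generate a synthetic behavioral session
#'
#' Draws choices for every cell of a trial design from the observer's
#' closed-form choice probability (or, with `method = "simulate"`, from
#' trial-by-trial Euler simulation of the integrator), producing a
#' [choice_table()] with known ground truth. The default design is the
#' 7 x 7 psychometric matrix, whose extremes (delta_T of +/-0.35, delta_I
#' of +/-0.3) provide the easy trials.
#'
#' @param observer A [synthetic_observer()].
#' @param design A trial design from [build_trial_matrix()].
#' @param n_trials_per_cell Trials per design cell.
#' @param rng_seed Seed; regeneration is deterministic.
#' @param method `"closed_form"` (default) or `"simulate"`.
#' @return A `"choice_table"` with attribute `"p_true"` (the generating
#'   per-cell probabilities).
#' @export
make_behavior_session <- function(observer,
                                  design = build_trial_matrix("duration"),
                                  n_trials_per_cell = 100L, rng_seed = 1L,
                                  method = c("closed_form", "simulate")) {
  method <- match.arg(method)
  stopifnot(inherits(observer, "synthetic_observer"), nrow(design) >= 1)
  p_true <- vapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    observer_choice_prob(observer, row$T1, row$T2, row$I1, row$I2,
                         row$light)
  }, numeric(1L))
  n_chose2 <- if (method == "closed_form") {
    withr_seed(rng_seed,
               stats::rbinom(nrow(design), n_trials_per_cell, p_true))
  } else {
    seeds <- derive_seeds(rng_seed, nrow(design))
    g <- function(I) 1 + observer$coupling * (I / observer$reference_I - 1)
    vapply(seq_len(nrow(design)), function(i) {
      row <- design[i, ]
      b1 <- if (row$light == "excite_stim1") observer$light_boost else 1
      b2 <- if (row$light %in% c("excite_stim2", "inhibit_stim2"))
        observer$light_boost else 1
      withr_seed(seeds[i], {
        y1 <- simulate_percept(rep(observer$base_rate * g(row$I1) * b1,
                                   row$T1),
                               observer$percept, n_trials_per_cell,
                               rng_seed = NULL)
        y2 <- simulate_percept(rep(observer$base_rate * g(row$I2) * b2,
                                   row$T2),
                               observer$percept, n_trials_per_cell,
                               rng_seed = NULL)
        lapse <- stats::runif(n_trials_per_cell) < observer$percept$p_L
        choice <- ifelse(lapse,
                         stats::runif(n_trials_per_cell) < observer$percept$b_L,
                         y2 > y1)
        sum(choice)
      })
    }, numeric(1L))
  }
  out <- choice_table(delta_T = design$delta_T, delta_I = design$delta_I,
                      n_trials = n_trials_per_cell, n_chose2 = n_chose2,
                      light = design$light,
                      congruence = design$congruence)
  attr(out, "p_true") <- p_true
  out
}

#' Generate labeled spike rasters for a set of conditions
#'
#' Simulates rasters from a known neuron population under each condition of
#' a table (duration, light, optional intensity gain), either per neuron or
#' collapsed to the population-summed count (the sum of independent Poisson
#' units is drawn directly as Poisson of the summed rate).
#'
#' @param population A list of [neuron_params()] (or a single one).
#' @param conditions Data frame with columns `T`, `light` and optionally
#'   `intensity_gain`; must include at least one light-off condition.
#' @param n_trials Trials per condition.
#' @param t_pre Baseline epoch before stimulus onset, ms.
#' @param t_post Tail recorded after stimulus offset, ms.
#' @param rng_seed Seed.
#' @param collapse Sum over neurons (`TRUE`, default) or return per-neuron
#'   rasters (a list of lists).
#' @return A list over conditions of `"spike_raster"` (collapsed) or lists
#'   of per-neuron rasters.
#' @export
make_raster_set <- function(population, conditions, n_trials = 100L,
                            t_pre = 0, t_post = 0, rng_seed = 1L,
                            collapse = TRUE) {
  if (inherits(population, "neuron_params")) population <- list(population)
  if (!"light" %in% names(conditions)) conditions$light <- FALSE
  if (!any(!conditions$light))
    stop("conditions must include at least one light-off condition")
  if (!"intensity_gain" %in% names(conditions)) conditions$intensity_gain <- 1
  seeds <- derive_seeds(rng_seed, nrow(conditions) * length(population))
  sm <- matrix(seeds, nrow(conditions), length(population))
  lapply(seq_len(nrow(conditions)), function(ci) {
    cond <- conditions[ci, ]
    t <- seq.int(-t_pre, cond$T + t_post - 1)
    if (collapse) {
      rate <- population_rate(population, cond$T, light = cond$light,
                              t = t, intensity_gain = cond$intensity_gain)
      counts <- withr_seed(sm[ci, 1L], matrix(
        stats::rpois(n_trials * length(t), rep(rate, each = n_trials)),
        nrow = n_trials))
      structure(
        list(counts = counts, time_ms = t, bin_width = 1, rate = rate,
             condition = list(T = cond$T, light = cond$light,
                              intensity_gain = cond$intensity_gain)),
        class = "spike_raster")
    } else {
      lapply(seq_along(population), function(ni) {
        simulate_spikes(population[[ni]], T = cond$T, n_trials = n_trials,
                        light = cond$light, t_pre = t_pre, t_post = t_post,
                        rng_seed = sm[ci, ni],
                        intensity_gain = cond$intensity_gain)
      })
    }
  })
}

#' Serialize / restore a ground-truth record
#'
#' A ground-truth record (observer, population parameters, design, seeds)
#' fully determines every synthetic dataset; regeneration from the restored
#' record is bit-identical.
#'
#' @param truth A list with any of `observer` ([synthetic_observer()]),
#'   `population` (list of [neuron_params()]), `design` (data frame),
#'   `seeds` (named integers).
#' @param path JSON path.
#' @export
write_ground_truth_json <- function(truth, path) {
  rec <- list()
  if (!is.null(truth$observer)) {
    o <- truth$observer
    rec$observer <- c(as.list(unlist(o$percept)),
                      list(coupling = o$coupling, base_rate = o$base_rate,
                           reference_I = o$reference_I,
                           light_boost = o$light_boost))
  }
  if (!is.null(truth$population))
    rec$population <- lapply(truth$population, function(p) as.list(unlist(p)))
  if (!is.null(truth$design)) rec$design <- truth$design
  if (!is.null(truth$seeds)) rec$seeds <- as.list(truth$seeds)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(rec$observer)) {
    o <- rec$observer
    out$observer <- synthetic_observer(
      percept = percept_params(tau = o$tau, mu_b = o$mu_b,
                               sigma2_b = o$sigma2_b, p_L = o$p_L,
                               b_L = o$b_L),
      coupling = o$coupling, base_rate = o$base_rate,
      reference_I = o$reference_I,
      light_boost = if (!is.null(o$light_boost)) o$light_boost else 1.3)
  }
  if (!is.null(rec$population)) {
    pop <- rec$population
    if (is.data.frame(pop))   # simplified from the JSON array of records
      pop <- lapply(seq_len(nrow(pop)), function(i) as.list(pop[i, ]))
    out$population <- lapply(pop,
                             function(p) do.call(neuron_params, as.list(p)))
  }
  if (!is.null(rec$design)) out$design <- as.data.frame(rec$design)
  if (!is.null(rec$seeds)) out$seeds <- unlist(rec$seeds)
  out
}

#' End-to-end parameter-recovery experiment
#'
#' Generates data from known ground truth and runs the requested fitting
#' stages, comparing the recovered parameters with the generating ones
#' against stated tolerances. Stages: `"lnp"` (single-neuron fit, free
#' parameters within `tol_lnp`), `"mixture"` (two-cluster assignment
#' accuracy at least `tol_mixture`), `"percept"` (tau within `tol_tau`
#' relative, p_L within `tol_pL` absolute), `"psychometric"` (generating
#' parameters inside the central 95% bootstrap interval).
#'
#' @param stages Which stages to run.
#' @param rng_seed Master seed.
#' @param n_trials_lnp Trials per condition for the LNP recovery.
#' @param n_behavior_trials Total behavioral trials for the percept
#'   recovery (spread over the 7 x 7 design).
#' @param n_psy_trials Trials per level for the psychometric recovery.
#' @param tol_lnp,tol_mixture,tol_tau,tol_pL Tolerances (see above).
#' @return An object of class `"recovery_report"`: per-stage lists with
#'   `true`, `fitted`, the comparison metric and a `pass` flag.
#' @export
recovery_experiment <- function(stages = c("lnp", "mixture", "percept",
                                           "psychometric"),
                                rng_seed = 1L, n_trials_lnp = 200L,
                                n_behavior_trials = 10000L,
                                n_psy_trials = 500L,
                                tol_lnp = 0.2, tol_mixture = 0.95,
                                tol_tau = 0.2, tol_pL = 0.05) {
  stages <- match.arg(stages, several.ok = TRUE)
  seeds <- derive_seeds(rng_seed, 8L)
  report <- list()

  if ("lnp" %in% stages) {
    # ground truth placed in the sensitive range of the I/F sigmoid so all
    # eight parameters are identifiable from the PSTHs
    truth <- neuron_params(I0 = -0.3, I1_ss = 0.2, I1_peak = 0.45,
                           I2_ss = 0.15, I2_peak = 0.3, I3_peak = -0.25,
                           lambda_max = 0.08, upsilon = 1)
    # conditions probe several points of the I/F curve (two intensities x
    # light on/off), as in the recorded stimulus set; this is what makes
    # the nonlinearity scale identifiable
    conds <- expand.grid(gain = c(0.3, 0.6, 1, 1.5), light = c(FALSE, TRUE))
    sub_seeds <- derive_seeds(seeds[1L], nrow(conds))
    psths <- lapply(seq_len(nrow(conds)), function(i) {
      r <- simulate_spikes(truth, T = 500, n_trials = n_trials_lnp,
                           light = conds$light[i], t_pre = 400,
                           t_post = 150, rng_seed = sub_seeds[i],
                           intensity_gain = conds$gain[i])
      bin_psth(r)
    })
    fit <- fit_lnp(psths, rng_seed = seeds[3L])
    true_v <- unlist(truth[lnp_free_names])
    fit_v <- unlist(fit$params[lnp_free_names])
    rel <- abs(fit_v - true_v) / pmax(abs(true_v), 0.1)
    report$lnp <- list(true = true_v, fitted = fit_v, rel_error = rel,
                       tolerance = tol_lnp, pass = all(rel <= tol_lnp))
  }

  if ("mixture" %in% stages) {
    # a two-class population of the size of the recorded data set
    nmix <- 120L
    half <- nmix / 2
    centers <- rbind(c(-0.5, 0.3, 1.2, 0, 0, 0, 0.12, 1),
                     c(0.5, 1.2, 2.5, 0.5, 1, -0.3, 0.25, 2))
    X <- withr_seed(seeds[4L], {
      lab <- rep(1:2, each = half)
      jitter <- matrix(stats::rnorm(nmix * 8, 0, 0.08), nmix, 8)
      centers[lab, ] + jitter
    })
    colnames(X) <- lnp_free_names
    mix <- fit_neuron_mixture(X, G = 5, rng_seed = seeds[5L])
    lab <- rep(1:2, each = half)
    acc <- cluster_accuracy(lab, mix$assignments)
    report$mixture <- list(accuracy = acc, weights = mix$weights,
                           tolerance = tol_mixture,
                           pass = acc >= tol_mixture)
  }

  if ("percept" %in% stages) {
    # light-off plus photoexcitation of either stimulus: the three drive
    # regimes jointly identify tau
    obs <- synthetic_observer()
    design <- rbind(build_trial_matrix("duration"),
                    build_trial_matrix("duration",
                                       light_condition = "excite_stim2"),
                    build_trial_matrix("duration",
                                       light_condition = "excite_stim1"))
    n_cell <- max(1L, round(n_behavior_trials / nrow(design)))
    beh <- make_behavior_session(obs, design, n_cell, rng_seed = seeds[6L])
    drives <- constant_drive_set(design, obs$base_rate,
                                 coupling = obs$coupling,
                                 reference_I = obs$reference_I,
                                 light_boost = obs$light_boost)
    fit <- fit_percept(beh, drives, rng_seed = seeds[6L])
    tau_err <- abs(fit$params$tau - obs$percept$tau) / obs$percept$tau
    pL_err <- abs(fit$params$p_L - obs$percept$p_L)
    report$percept <- list(
      true = unlist(obs$percept), fitted = unlist(fit$params),
      tau_rel_error = tau_err, pL_abs_error = pL_err,
      pass = tau_err <= tol_tau && pL_err <= tol_pL)
  }

  if ("psychometric" %in% stages) {
    gen <- c(gamma = 0.05, lambda_u = 0.05, u = 0, nu = 0.1)
    levels <- seq(-0.35, 0.35, length.out = 7)
    p <- psychometric_curve(levels, gen["gamma"], gen["lambda_u"],
                            gen["u"], gen["nu"])
    k <- withr_seed(seeds[7L], stats::rbinom(length(p), n_psy_trials, p))
    tb <- choice_table(delta_T = levels, delta_I = 0,
                       n_trials = n_psy_trials, n_chose2 = k)
    boot <- bootstrap_psychometric(tb, "duration", n_boot = 200L,
                                   rng_seed = seeds[8L])
    ci <- apply(boot[, c("gamma", "lambda_u", "u", "nu")], 2L,
                stats::quantile, probs = c(0.025, 0.975))
    inside <- gen >= ci[1L, ] & gen <= ci[2L, ]
    fit <- fit_psychometric(tb, "duration")
    report$psychometric <- list(true = gen, fitted = fit$par, ci = ci,
                                inside_ci = inside, pass = all(inside))
  }

  structure(report, class = "recovery_report")
}

# Best assignment accuracy over all mappings of predicted clusters to the
# (few) true labels.
cluster_accuracy <- function(truth, assigned) {
  labs <- sort(unique(truth))
  clusters <- sort(unique(assigned))
  correct <- sum(vapply(clusters, function(cl) {
    max(vapply(labs, function(l) sum(truth == l & assigned == cl),
               numeric(1L)))
  }, numeric(1L)))
  correct / length(truth)
}

#' Constant-profile drive set for a trial design
#'
#' The synthetic observer's drive model: each stimulus delivers a constant
#' summed rate, scaled by the intensity coupling and by the photoexcitation
#' boost of the row's light condition. Used to fit the percept model to
#' observer-generated behavior.
#'
#' @param design A trial design (see [build_trial_matrix()]).
#' @param base_rate Drive during the stimulus, spikes/ms.
#' @param coupling,reference_I Intensity-to-drive coupling and reference.
#' @param light_boost Drive multiplier for a photoexcited stimulus.
#' @return A `"drive_set"`.
#' @export
constant_drive_set <- function(design, base_rate, coupling = 0,
                               reference_I = 64, light_boost = 1.3) {
  g <- function(I) 1 + coupling * (I / reference_I - 1)
  profiles <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    b1 <- if (row$light == "excite_stim1") light_boost else 1
    b2 <- if (row$light %in% c("excite_stim2", "inhibit_stim2"))
      light_boost else 1
    list(stim1 = rep(base_rate * g(row$I1) * b1, row$T1),
         stim2 = rep(base_rate * g(row$I2) * b2, row$T2))
  })
  structure(list(profiles = profiles, design = design), class = "drive_set")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery report\n")
  for (nm in names(x)) {
    st <- x[[nm]]
    cat(sprintf("  %-13s %s", nm, if (st$pass) "PASS" else "FAIL"))
    extra <- switch(nm,
      lnp = sprintf(" (max relative error %.3f)", max(st$rel_error)),
      mixture = sprintf(" (assignment accuracy %.3f)", st$accuracy),
      percept = sprintf(" (tau error %.3f, p_L error %.3f)",
                        st$tau_rel_error, st$pL_abs_error),
      psychometric = sprintf(" (%d/%d parameters in 95%% CI)",
                             sum(st$inside_ci), length(st$inside_ci)),
      "")
    cat(extra, "\n")
  }
  invisible(x)
}
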