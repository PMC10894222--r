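#' Default pipeline configuration
#'
#' All numeric defaults follow the study design where printed: 10-ms fit
#' bins, 1-ms PSTH steps, 25-ms smoothing sigma, the 2.2-STD onset
#' threshold, 1000 resampling iterations, G = 5 mixture classes with
#' concentration 1e-6, tau regularization weight 0.01 centered at 600 ms,
#' a 5000-neuron full-scale population with 100 proxies. Desk-scale sizes
#' (200 neurons, 100 trials per condition, 3 proxies) keep the demo fast;
#' set `full_scale = TRUE` for the reference sizes.
#'
#' @param full_scale Use the full-scale population sizes.
#' @param seed Master seed; every random stage derives its own seed from it.
#' @return A nested list of per-module settings.
#' @export
default_config <- function(full_scale = FALSE, seed = 1L) {
  list(
    seed = as.integer(seed),
    stimgen = list(sample_rate_khz = 1, n_seeds = 50L,
                   reference_T = 334, reference_I = 64,
                   durations = design_levels(161, 694),
                   intensities = design_levels(34, 119)),
    lnp = list(fit_bin_ms = 10, taus = c(tau_M = 48, tau_O = 49, tau_I = 28),
               current_bounds = c(-5, 5)),
    mixture = list(G = 5L, alpha = 1e-6,
                   n_neurons = if (full_scale) 5000L else 200L,
                   n_proxies = if (full_scale) 100L else 3L),
    percept = list(reg_weight = 0.01, reg_center = 600),
    psychometrics = list(n_boot = 1000L, n_permutations = 1000L,
                         svm_folds = 10L),
    neural = list(psth_step_ms = 1, smoothing_sigma = 25,
                  onset_threshold_std = 2.2,
                  zscore_baseline = c(-800, 0),
                  onset_baseline = c(-480, -20),
                  endwindow_ms = 100, coding_fraction = 0.9),
    synthetic = list(n_trials_per_cell = 100L,
                     n_trials_per_condition = 100L))
}

#' Read a pipeline configuration from JSON
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path JSON file with per-module sections.
#' @param full_scale Passed to [default_config()].
#' @return A configuration list.
#' @export
read_config <- function(path, full_scale = FALSE) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config(full_scale = full_scale,
                        seed = if (!is.null(user$seed)) user$seed else 1L)
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_into(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_into(cfg, user)
}

#' Run the synthetic analysis pipeline
#'
#' Executes the requested stages in dependency order on synthetic data:
#' `"stimuli"` (vibration traces and the trial matrix), `"neurons"`
#' (simulate a ground-truth population and fit the LNP model to a subset),
#' `"mixture"` (fit the parameter mixture and sample a surrogate
#' population), `"percept"` (generate behavior, build drives, fit the
#' percept model, predict the neurometric curve), `"behavior"`
#' (psychometric fit and bias measures on the generated session), and
#' `"recovery"` (the [recovery_experiment()]). Each random stage derives
#' and logs its seed from `config$seed`; a rerun with the same
#' configuration reproduces all outputs exactly.
#'
#' @param config A configuration list from [default_config()] or
#'   [read_config()].
#' @param stages Character vector of stages (default all).
#' @param out_dir Optional directory: stage outputs are written there as
#'   CSV/JSON.
#' @param verbose Print stage progress.
#' @return An object of class `"pipeline_report"`: per-stage results,
#'   seeds and wall times.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("stimuli", "neurons", "mixture",
                                    "percept", "behavior", "recovery"),
                         out_dir = NULL, verbose = FALSE) {
  if (length(stages))
    stages <- match.arg(stages, c("stimuli", "neurons", "mixture",
                                  "percept", "behavior", "recovery"),
                        several.ok = TRUE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 16L)
  report <- list(config_seed = config$seed, stages = list())
  say <- function(...) if (verbose) message(sprintf(...))
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- fun()
    report$stages[[name]] <<- c(res, list(
      wall_s = round(proc.time()[["elapsed"]] - t0, 2)))
    say("stage %-9s done in %.1fs", name, report$stages[[name]]$wall_s)
  }

  if ("stimuli" %in% stages) run_stage("stimuli", function() {
    sg <- config$stimgen
    design <- build_trial_matrix("duration",
                                 durations = sg$durations,
                                 intensities = sg$intensities,
                                 reference_T = sg$reference_T,
                                 reference_I = sg$reference_I)
    stim <- generate_vibration(sigma = sg$reference_I / sqrt(2 / pi),
                               duration_ms = sg$reference_T,
                               rng_seed = seeds[1L])
    state$design <- design
    if (!is.null(out_dir))
      utils::write.csv(design, file.path(out_dir, "trial_matrix.csv"),
                       row.names = FALSE)
    list(seed = seeds[1L], n_trial_types = nrow(design),
         example_intensity = mean(abs(stim$velocity_trace)))
  })

  if ("neurons" %in% stages) run_stage("neurons", function() {
    truth <- neuron_params(I0 = -0.5, I1_ss = 0.6, I1_peak = 1.5,
                           I2_ss = 0.4, I2_peak = 0.8, I3_peak = -0.2,
                           lambda_max = 0.08, upsilon = 1)
    r_off <- simulate_spikes(truth, T = 334, n_trials =
                               config$synthetic$n_trials_per_condition,
                             t_pre = 200, t_post = 100, rng_seed = seeds[2L])
    r_on <- simulate_spikes(truth, T = 334, n_trials =
                              config$synthetic$n_trials_per_condition,
                            light = TRUE, t_pre = 200, t_post = 100,
                            rng_seed = seeds[3L])
    fit <- fit_lnp(list(bin_psth(r_off, config$lnp$fit_bin_ms),
                        bin_psth(r_on, config$lnp$fit_bin_ms)),
                   taus = config$lnp$taus, rng_seed = seeds[4L])
    state$lnp_truth <- truth
    state$lnp_fit <- fit
    if (!is.null(out_dir))
      write_neuron_json(list(unit1 = fit),
                        file.path(out_dir, "lnp_fit.json"))
    list(seed = seeds[2L], fit_quality = fit$fit_quality,
         params = unlist(fit$params[lnp_free_names]))
  })

  if ("mixture" %in% stages) run_stage("mixture", function() {
    base <- if (!is.null(state$lnp_fit)) unlist(state$lnp_fit$params[lnp_free_names])
            else c(I0 = -0.5, I1_ss = 0.6, I1_peak = 1.5, I2_ss = 0.4,
                   I2_peak = 0.8, I3_peak = -0.2, lambda_max = 0.08,
                   upsilon = 1)
    X <- withr_seed(seeds[5L], {
      n <- 40L
      sweep(matrix(stats::rnorm(n * 8, 0,
                                pmax(abs(base) * 0.2, 0.02)), n, 8,
                   byrow = TRUE),
            2L, base, "+")
    })
    colnames(X) <- lnp_free_names
    mix <- fit_neuron_mixture(X, G = config$mixture$G,
                              alpha = config$mixture$alpha,
                              rng_seed = seeds[6L])
    pop <- sample_population(mix, n = config$mixture$n_neurons,
                             rng_seed = seeds[7L])
    state$mixture <- mix
    state$population <- pop
    if (!is.null(out_dir))
      write_mixture_json(mix, file.path(out_dir, "mixture.json"))
    list(seed = seeds[5L], weights = mix$weights,
         n_neurons = length(pop),
         n_rejected = attr(pop, "n_rejected"))
  })

  if ("percept" %in% stages) run_stage("percept", function() {
    design <- if (!is.null(state$design)) state$design
              else build_trial_matrix("duration")
    obs <- synthetic_observer()
    beh <- make_behavior_session(obs, design,
                                 config$synthetic$n_trials_per_cell,
                                 rng_seed = seeds[8L])
    drives <- constant_drive_set(design, obs$base_rate,
                                 coupling = obs$coupling,
                                 reference_I = obs$reference_I)
    fit <- fit_percept(beh, drives,
                       reg_weight = config$percept$reg_weight,
                       reg_center = config$percept$reg_center,
                       rng_seed = seeds[9L])
    curve <- neurometric_curve(drives, fit)
    state$behavior <- beh
    state$percept_fit <- fit
    if (!is.null(out_dir)) {
      utils::write.csv(curve, file.path(out_dir, "neurometric_curve.csv"),
                       row.names = FALSE)
      jsonlite::write_json(as.list(unlist(fit$params)),
                           file.path(out_dir, "percept_params.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(seed = seeds[8L], params = unlist(fit$params),
         pse = curve_pse(curve$delta_T, curve$p_choice))
  })

  if ("behavior" %in% stages) run_stage("behavior", function() {
    beh <- if (!is.null(state$behavior)) state$behavior else {
      make_behavior_session(synthetic_observer(),
                            n_trials_per_cell =
                              config$synthetic$n_trials_per_cell,
                            rng_seed = seeds[10L])
    }
    fit <- fit_psychometric(beh, "duration")
    bias <- bias_measure(beh, "duration")
    if (!is.null(out_dir)) {
      write_choice_csv(beh, file.path(out_dir, "behavior_session.csv"))
      utils::write.csv(bias, file.path(out_dir, "bias_measure.csv"),
                       row.names = FALSE)
    }
    list(seed = seeds[10L], pse = fit$pse, slope = fit$slope,
         psychometric = fit$par, bias_range = range(bias$bias_percent))
  })

  if ("recovery" %in% stages) run_stage("recovery", function() {
    rec <- recovery_experiment(stages = c("mixture", "psychometric"),
                               rng_seed = seeds[11L])
    list(seed = seeds[11L],
         pass = vapply(rec, `[[`, logical(1L), "pass"))
  })

  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (seed %d): %d stage%s\n", x$config_seed,
              length(x$stages), if (length(x$stages) == 1) "" else "s"))
  for (nm in names(x$stages))
    cat(sprintf("  %-9s seed %-10d %6.1fs\n", nm,
                x$stages[[nm]]$seed %||% NA_integer_,
                x$stages[[nm]]$wall_s))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
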