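#' Mean drive profiles for every trial of a design
#'
#' Computes, for each row of a trial design, the expected summed population
#' rate profile of stimulus 1 and stimulus 2, honoring the row's light
#' condition (`excite_stim1`, `excite_stim2` and `inhibit_stim2` turn the
#' optogenetic currents on for the corresponding stimulus; the sign of the
#' population's opto currents decides excitation vs suppression). An
#' optional intensity-to-drive coupling scales the mechanoreceptor currents
#' by `1 + coupling * (I/reference_I - 1)`, the mechanism by which vibration
#' intensity biases perceived duration.
#'
#' Profiles are cached over unique (duration, light, gain) combinations.
#'
#' @param population A list of [neuron_params()] (one population proxy).
#' @param design A data frame with columns `T1, T2, I1, I2, light` (see
#'   [build_trial_matrix()]).
#' @param coupling Intensity-to-drive coupling coefficient (0 = none).
#' @param reference_I Reference intensity, mm/s.
#' @return An object of class `"drive_set"`: a list with `$profiles`
#'   (per-row lists with `stim1`, `stim2` rate vectors) and `$design`.
#' @export
drive_profiles <- function(population, design, coupling = 0,
                           reference_I = 64) {
  need <- c("T1", "T2", "I1", "I2", "light")
  if (!all(need %in% names(design)))
    stop("design must have columns ", paste(need, collapse = ", "))
  gain <- function(I) 1 + coupling * (I / reference_I - 1)
  cache <- new.env(parent = emptyenv())
  profile <- function(T, light, g) {
    key <- sprintf("%.6g|%d|%.6g", T, as.integer(light), g)
    if (is.null(cache[[key]]))
      cache[[key]] <- population_rate(population, T, light = light,
                                      intensity_gain = g)
    cache[[key]]
  }
  profiles <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    list(
      stim1 = profile(row$T1, row$light == "excite_stim1", gain(row$I1)),
      stim2 = profile(row$T2,
                      row$light %in% c("excite_stim2", "inhibit_stim2"),
                      gain(row$I2)))
  })
  structure(list(profiles = profiles, design = design), class = "drive_set")
}

# Predicted choice probabilities for one drive set under given parameters.
predict_choice_probs <- function(drive_set, params) {
  vapply(seq_along(drive_set$profiles), function(i) {
    pr <- drive_set$profiles[[i]]
    row <- drive_set$design[i, ]
    p1 <- integrate_percept(pr$stim1, params, T = row$T1)
    p2 <- integrate_percept(pr$stim2, params, T = row$T2)
    choice_probability(p1, p2, params)
  }, numeric(1L))
}

#' Fit the percept-model parameters to choice data
#'
#' Maximum-likelihood estimation of the five behavioral parameters (tau,
#' mu_b, sigma2_b, p_L, b_L) common to all supplied population proxies, by
#' maximizing the binomial log-likelihood of the observed choices under the
#' lapse-aware choice rule, with an L2 regularization on tau of weight
#' `reg_weight` centered at `reg_center` (penalty
#' `reg_weight * ((tau - reg_center)/reg_center)^2`; the normalization by
#' the center makes the weight dimensionless). Optimization runs over
#' (log tau, mu_b, log sigma2_b, logit p_L, logit b_L) with multi-start
#' Nelder-Mead.
#'
#' @param behavior A choice table: data frame with columns
#'   `T1, T2, I1, I2, light, n_trials, n_chose2`.
#' @param drives A `"drive_set"` (from [drive_profiles()]) or a list of them
#'   (independent population proxies; the log-likelihood sums over proxies).
#' @param reg_weight,reg_center L2 regularization weight and center (ms)
#'   for tau.
#' @param init Optional [percept_params()] starting point.
#' @param n_starts Number of optimization starts.
#' @param rng_seed Seed for start jitter.
#' @return An object of class `"percept_fit"`: `$params`
#'   ([percept_params()]), `$logLik`, `$penalty`, `$convergence` (non-zero
#'   flagged with a warning), `$fitted` (per-condition predicted
#'   probabilities, averaged over proxies), `$behavior`, `$drives`.
#' @export
fit_percept <- function(behavior, drives, reg_weight = 0.01,
                        reg_center = 600, init = NULL, n_starts = 3L,
                        rng_seed = 1L) {
  if (inherits(drives, "drive_set")) drives <- list(drives)
  if (!length(drives)) stop("need at least one population proxy")
  need <- c("n_trials", "n_chose2")
  if (!all(need %in% names(behavior)))
    stop("behavior must have columns n_trials and n_chose2")
  for (ds in drives)
    if (nrow(ds$design) != nrow(behavior))
      stop("drive set and behavior table have different numbers of conditions")

  k <- behavior$n_chose2
  n <- behavior$n_trials

  unpack <- function(th) {
    percept_params(tau = exp(th[1L]), mu_b = th[2L],
                   sigma2_b = exp(th[3L]),
                   p_L = expit(th[4L]), b_L = expit(th[5L]))
  }
  nll <- function(th) {
    pars <- try(unpack(th), silent = TRUE)
    if (inherits(pars, "try-error")) return(1e10)
    ll <- 0
    for (ds in drives) {
      p <- predict_choice_probs(ds, pars)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- ll + sum(k * log(p) + (n - k) * log(1 - p))
    }
    pen <- reg_weight * ((pars$tau - reg_center) / reg_center)^2
    if (!is.finite(ll)) return(1e10)
    -ll + pen
  }

  th0 <- if (is.null(init))
    c(log(reg_center), 0, log(1), logit(0.05), logit(0.5))
  else
    c(log(init$tau), init$mu_b, log(max(init$sigma2_b, 1e-8)),
      logit(min(max(init$p_L, 1e-4), 1 - 1e-4)),
      logit(min(max(init$b_L, 1e-4), 1 - 1e-4)))

  jit <- withr_seed(rng_seed, lapply(seq_len(n_starts), function(i) {
    if (i == 1L) rep(0, 5L) else stats::rnorm(5L, 0, c(0.5, 0.5, 1, 1, 0.5))
  }))
  fits <- lapply(jit, function(j) {
    try(stats::optim(th0 + j, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10)),
        silent = TRUE)
  })
  fits <- Filter(function(f) !inherits(f, "try-error"), fits)
  if (!length(fits)) stop("percept-model optimization failed from all starts")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
  if (best$convergence != 0)
    warning("percept-model fit did not fully converge; best candidate returned")

  pars <- unpack(best$par)
  pen <- reg_weight * ((pars$tau - reg_center) / reg_center)^2
  fitted <- rowMeans(vapply(drives, predict_choice_probs,
                            numeric(nrow(behavior)), params = pars))
  structure(
    list(params = pars, logLik = -(best$value - pen), penalty = pen,
         convergence = best$convergence, fitted = fitted,
         behavior = behavior, drives = drives,
         reg_weight = reg_weight, reg_center = reg_center),
    class = "percept_fit")
}

#' @export
coef.percept_fit <- function(object, ...) unlist(object$params)

#' @export
logLik.percept_fit <- function(object, ...) {
  structure(object$logLik, df = 5L, class = "logLik")
}

#' @export
print.percept_fit <- function(x, ...) {
  cat(sprintf("Leaky-integrator percept fit (%s)\n",
              if (x$convergence == 0) "converged" else "NOT converged"))
  print(x$params)
  cat(sprintf("logLik %.1f (tau penalty %.4f), %d conditions, %d population prox%s\n",
              x$logLik, x$penalty, nrow(x$behavior), length(x$drives),
              if (length(x$drives) > 1) "ies" else "y"))
  invisible(x)
}

#' @export
summary.percept_fit <- function(object, ...) {
  resid <- object$behavior$n_chose2 / object$behavior$n_trials - object$fitted
  out <- list(params = unlist(object$params), logLik = object$logLik,
              rmse = sqrt(mean(resid^2)), n_conditions = nrow(object$behavior),
              n_proxies = length(object$drives),
              convergence = object$convergence)
  class(out) <- "summary.percept_fit"
  out
}

#' @export
print.summary.percept_fit <- function(x, ...) {
  cat("Percept-model fit summary\n")
  print(round(x$params, 4))
  cat(sprintf("  logLik %.1f, RMSE of choice proportions %.4f (%d conditions, %d proxies)\n",
              x$logLik, x$rmse, x$n_conditions, x$n_proxies))
  invisible(x)
}

#' @export
predict.percept_fit <- function(object, drives = NULL, ...) {
  if (is.null(drives)) return(object$fitted)
  if (inherits(drives, "drive_set")) drives <- list(drives)
  rowMeans(vapply(drives, predict_choice_probs,
                  numeric(nrow(drives[[1L]]$design)), params = object$params))
}

#' @export
residuals.percept_fit <- function(object, ...) {
  object$behavior$n_chose2 / object$behavior$n_trials - object$fitted
}

#' @export
simulate.percept_fit <- function(object, nsim = 1L, seed = 1L, ...) {
  p <- object$fitted
  n <- object$behavior$n_trials
  withr_seed(seed, replicate(nsim, stats::rbinom(length(p), n, p),
                             simplify = FALSE))
}

#' Neurometric choice curve predicted from population activity
#'
#' Evaluates the fitted (or supplied) percept model on the drive profiles of
#' a trial design and aggregates the predicted probability of judging
#' stimulus 2 longer by normalized duration difference and light condition
#' — the model counterpart of the behavioral psychometric curve. With a
#' photoexcitation drive on stimulus 2, the predicted curve lies above the
#' no-light curve and its PSE moves leftward (perceived duration dilates).
#'
#' @param drives A `"drive_set"` or list of them.
#' @param params A [percept_params()] or a `"percept_fit"`.
#' @return A data frame `delta_T, light, p_choice` (one row per unique
#'   combination; probabilities averaged over intensities and proxies).
#' @export
neurometric_curve <- function(drives, params) {
  if (inherits(params, "percept_fit")) params <- params$params
  if (inherits(drives, "drive_set")) drives <- list(drives)
  design <- drives[[1L]]$design
  p <- rowMeans(vapply(drives, predict_choice_probs,
                       numeric(nrow(design)), params = params))
  dT <- round(delta_T(design$T1, design$T2), 6)
  agg <- stats::aggregate(p, list(delta_T = dT, light = design$light), mean)
  names(agg)[3L] <- "p_choice"
  agg[order(agg$light, agg$delta_T), ]
}
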