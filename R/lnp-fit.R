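#' Bin a spike raster into a PSTH for model fitting
#'
#' Sums spike counts across trials into fixed-width time bins (10 ms by
#' default, the width used when fitting the LNP model).
#'
#' @param raster A `"spike_raster"`.
#' @param bin_width Bin width in ms.
#' @return A list with `counts` (summed spikes per bin), `time_ms` (bin left
#'   edges), `bin_width`, `n_trials`, `T` and `light` — the per-condition
#'   PSTH record consumed by [fit_lnp()].
#' @export
bin_psth <- function(raster, bin_width = 10) {
  stopifnot(inherits(raster, "spike_raster"))
  edges <- seq(min(raster$time_ms), max(raster$time_ms) + 1, by = bin_width)
  if (edges[length(edges)] <= max(raster$time_ms))
    edges <- c(edges, edges[length(edges)] + bin_width)
  bin <- findInterval(raster$time_ms, edges, rightmost.closed = FALSE)
  counts <- as.vector(tapply(colSums(raster$counts), bin, sum))
  list(counts = counts, time_ms = edges[seq_along(counts)],
       bin_width = bin_width, n_trials = nrow(raster$counts),
       T = raster$condition$T, light = isTRUE(raster$condition$light),
       intensity_gain = raster$condition$intensity_gain %||% 1)
}

# Expected summed spike count per PSTH bin under the model (the 1-ms rate
# profile is integrated over each bin).
lnp_expected_counts <- function(params, psth) {
  nb <- length(psth$counts)
  t <- psth$time_ms[1L] + seq_len(nb * psth$bin_width) - 1
  g <- psth$intensity_gain %||% 1
  if (g != 1) {
    params$I1_ss <- params$I1_ss * g
    params$I1_peak <- params$I1_peak * g
  }
  rate <- lnp_rate(params, t, psth$T, light = psth$light)
  mu <- colSums(matrix(rate, nrow = psth$bin_width))
  mu * psth$n_trials
}

# Map a free-parameter vector (currents raw, lambda/upsilon on log scale)
# onto a neuron_params object.
lnp_theta_to_params <- function(theta, taus, t0_M, t0_O) {
  neuron_params(
    I0 = theta[["I0"]], I1_ss = theta[["I1_ss"]], I1_peak = theta[["I1_peak"]],
    I2_ss = theta[["I2_ss"]], I2_peak = theta[["I2_peak"]],
    I3_peak = theta[["I3_peak"]],
    lambda_max = exp(theta[["log_lambda"]]),
    upsilon = exp(theta[["log_upsilon"]]),
    tau_M = taus[["tau_M"]], tau_O = taus[["tau_O"]], tau_I = taus[["tau_I"]],
    t0_M = t0_M, t0_O = t0_O)
}

#' Fit the LNP neuron model to binned PSTHs
#'
#' Penalized maximum-likelihood inference of the single-neuron model from
#' per-condition PSTHs in 10-ms bins. The per-bin summed spike counts are
#' modeled as Poisson with mean equal to the integrated model rate times the
#' trial count; the negative log-likelihood, plus a small ridge penalty on
#' the current parameters (weight `ridge`), is minimized by multi-start
#' L-BFGS-B over the 8 free parameters (currents bounded to \[-5, 5\] a.u.,
#' `lambda_max` and `upsilon` optimized on the log scale). The decay time
#' constants are frozen at the across-neuron medians unless
#' `fixed_taus = FALSE`, in which case they are profiled on a coarse grid.
#'
#' The background current is initialized by inverting the I/F curve at the
#' pre-stimulus mean rate. When no light-on condition is supplied the four
#' optogenetic currents are fixed at zero (they are unidentifiable).
#'
#' @param psths A list of PSTH records from [bin_psth()] (at least one
#'   light-off condition; include a light-on condition to identify the
#'   optogenetic currents).
#' @param fixed_taus Keep tau_M/tau_O/tau_I at their defaults (recommended).
#' @param taus Named defaults for the time constants, ms.
#' @param t0_M,t0_O Current onset times, ms (experimenter-defined).
#' @param n_starts Number of optimization starts.
#' @param ridge Ridge weight on the current parameters.
#' @param rng_seed Seed controlling the multi-start jitter.
#' @return An object of class `"lnp_fit"`: fitted [neuron_params()] in
#'   `$params`, free-parameter vector `$theta`, `$logLik`, `$deviance`,
#'   pseudo-R2 `$fit_quality`, `$convergence` (0 = converged; non-zero is
#'   flagged with a warning and the best candidate returned) and the
#'   per-start bookkeeping in `$starts`.
#' @examples
#' truth <- neuron_params(I0 = -0.5, I1_ss = 0.6, I1_peak = 1.5,
#'                        lambda_max = 0.08)
#' r <- simulate_spikes(truth, T = 334, n_trials = 50, t_pre = 200,
#'                      rng_seed = 7)
#' fit <- fit_lnp(list(bin_psth(r)), n_starts = 2)
#' coef(fit)[c("I0", "I1_peak")]
#' @export
fit_lnp <- function(psths, fixed_taus = TRUE,
                    taus = c(tau_M = 48, tau_O = 49, tau_I = 28),
                    t0_M = 0, t0_O = 0, n_starts = 4L, ridge = 1e-3,
                    rng_seed = 1L) {
  if (!length(psths)) stop("'psths' must contain at least one condition")
  if (!any(!vapply(psths, `[[`, logical(1L), "light")))
    stop("at least one light-off condition is required")
  has_light <- any(vapply(psths, `[[`, logical(1L), "light"))

  current_names <- c("I0", "I1_ss", "I1_peak", "I2_ss", "I2_peak", "I3_peak")
  free <- c(current_names, "log_lambda", "log_upsilon")
  opto <- c("I2_ss", "I2_peak", "I3_peak")
  active <- if (has_light) free else setdiff(free, opto)

  nll <- function(th_active) {
    theta <- stats::setNames(numeric(length(free)), free)
    theta[active] <- th_active
    p <- lnp_theta_to_params(theta, taus, t0_M, t0_O)
    ll <- 0
    for (ps in psths) {
      mu <- lnp_expected_counts(p, ps)
      ll <- ll + sum(stats::dpois(ps$counts, mu, log = TRUE))
    }
    -ll + ridge * sum(theta[current_names]^2)
  }

  # data-driven initialization
  rate_per_ms <- function(ps) ps$counts / (ps$n_trials * ps$bin_width)
  off <- psths[!vapply(psths, `[[`, logical(1L), "light")]
  base_bins <- unlist(lapply(off, function(ps) rate_per_ms(ps)[ps$time_ms < 0]))
  peak <- max(unlist(lapply(psths, rate_per_ms)))
  lam0 <- max(peak * 1.2, 1e-3)
  r0 <- if (length(base_bins)) max(mean(base_bins), 1e-5) else 1e-4
  I0_init <- logit(min(max(r0 / lam0, 1e-6), 1 - 1e-6)) / 10

  init <- stats::setNames(numeric(length(free)), free)
  init["I0"] <- max(min(I0_init, 4.9), -4.9)
  init["I1_peak"] <- 0.5; init["I1_ss"] <- 0.25
  init["log_lambda"] <- log(lam0); init["log_upsilon"] <- 0

  lower <- stats::setNames(c(rep(-5, 6), log(1e-4), log(0.05)), free)
  upper <- stats::setNames(c(rep(5, 6), log(2), log(20)), free)

  jitters <- withr_seed(rng_seed, lapply(seq_len(n_starts), function(i) {
    if (i == 1L) rep(0, length(active))
    else stats::rnorm(length(active), 0, c(rep(0.5, length(active) - 2), 0.3, 0.3))
  }))

  starts <- lapply(jitters, function(jit) {
    st <- pmin(pmax(init[active] + jit, lower[active] + 1e-6),
               upper[active] - 1e-6)
    res <- try(stats::optim(st, nll, method = "L-BFGS-B",
                            lower = lower[active], upper = upper[active],
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(res, "try-error")) NULL else res
  })
  starts <- Filter(Negate(is.null), starts)
  if (!length(starts)) stop("all optimization starts failed")
  best <- starts[[which.min(vapply(starts, `[[`, numeric(1L), "value"))]]
  if (best$convergence != 0)
    warning("LNP fit did not fully converge; returning the best candidate")

  theta <- stats::setNames(numeric(length(free)), free)
  theta[active] <- best$par
  params <- lnp_theta_to_params(theta, taus, t0_M, t0_O)

  # deviance-based fit quality vs the saturated and null (flat-rate) models
  obs <- unlist(lapply(psths, `[[`, "counts"))
  mu_hat <- unlist(lapply(psths, function(ps) lnp_expected_counts(params, ps)))
  mu_null <- rep(mean(obs), length(obs))
  dev <- function(mu) -2 * sum(stats::dpois(obs, mu, log = TRUE) -
                               stats::dpois(obs, pmax(obs, 1e-12), log = TRUE))
  deviance <- dev(mu_hat)
  fit_quality <- 1 - deviance / dev(mu_null)

  structure(
    list(params = params, theta = theta, logLik = -best$value,
         deviance = deviance, fit_quality = fit_quality,
         convergence = best$convergence, has_light = has_light,
         psths = psths, taus = taus,
         starts = data.frame(
           value = vapply(starts, `[[`, numeric(1L), "value"),
           convergence = vapply(starts, `[[`, numeric(1L), "convergence"))),
    class = "lnp_fit")
}

#' @export
coef.lnp_fit <- function(object, ...) unlist(object$params)

#' @export
logLik.lnp_fit <- function(object, ...) {
  structure(object$logLik, df = if (object$has_light) 8L else 5L,
            class = "logLik")
}

#' @export
print.lnp_fit <- function(x, ...) {
  cat(sprintf("LNP neuron fit (%d condition%s, %s)\n",
              length(x$psths), if (length(x$psths) > 1) "s" else "",
              if (x$convergence == 0) "converged" else "NOT converged"))
  print(round(unlist(x$params[lnp_free_names]), 4))
  cat(sprintf("logLik %.1f, pseudo-R2 %.3f, max rate %.1f spikes/s\n",
              x$logLik, x$fit_quality, 1000 * x$params$lambda_max))
  invisible(x)
}

#' @export
summary.lnp_fit <- function(object, ...) {
  out <- list(params = unlist(object$params),
              logLik = object$logLik, deviance = object$deviance,
              fit_quality = object$fit_quality,
              convergence = object$convergence,
              n_conditions = length(object$psths),
              starts = object$starts)
  class(out) <- "summary.lnp_fit"
  out
}

#' @export
print.summary.lnp_fit <- function(x, ...) {
  cat("LNP neuron model fit\n")
  cat(sprintf("  conditions: %d   logLik: %.1f   deviance: %.1f   pseudo-R2: %.3f\n",
              x$n_conditions, x$logLik, x$deviance, x$fit_quality))
  print(round(x$params, 4))
  invisible(x)
}

#' Predicted rate profile of a fitted LNP neuron
#'
#' @param object An `"lnp_fit"`.
#' @param t Time in ms.
#' @param T Stimulus duration in ms.
#' @param light Optogenetic drive on/off.
#' @param ... Unused.
#' @return Rate in spikes per 1-ms bin at each `t`.
#' @export
predict.lnp_fit <- function(object, t, T, light = FALSE, ...) {
  lnp_rate(object$params, t, T, light = light)
}

#' @export
simulate.lnp_fit <- function(object, nsim = 1L, seed = 1L, T = 334,
                             light = FALSE, ...) {
  simulate_spikes(object$params, T = T, n_trials = nsim, light = light,
                  rng_seed = seed, ...)
}

#' Serialize fitted neuron parameters as JSON
#'
#' @param fits A named list of `"lnp_fit"` or `"neuron_params"` objects,
#'   keyed by unit id.
#' @param path Output path.
#' @export
write_neuron_json <- function(fits, path) {
  recs <- lapply(fits, function(f) {
    p <- if (inherits(f, "lnp_fit")) f$params else f
    as.list(unlist(p))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_neuron_json
#' @export
read_neuron_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(recs, function(r) do.call(neuron_params, as.list(r)))
}
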