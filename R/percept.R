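#' Parameters of the stochastic leaky-integrator percept model
#'
#' Perceived elapsed time is modeled as a leaky integrator
#' \eqn{d\Upsilon/dt = -\Upsilon/\tau + f(t)} driven by summed vS1 spiking
#' plus ongoing background input unrelated to the stimulus. The percept of
#' total stimulus duration is \eqn{\Upsilon} at stimulus offset. Choices can
#' lapse with probability `p_L`, in which case the response follows the bias
#' `b_L` instead of the percepts.
#'
#' `mu_b` and `sigma2_b` are the steady-state mean and variance that the
#' background input contributes to the integrator (the background terms of
#' the closed-form moments are \eqn{\mu_b(1 - e^{-t/\tau})} and
#' \eqn{\sigma^2_b(1 - e^{-2t/\tau})}).
#'
#' @param tau Integrator time constant, ms (> 0).
#' @param mu_b Steady-state mean background contribution (percept units).
#' @param sigma2_b Steady-state background variance (>= 0).
#' @param p_L Lapse probability in \[0, 1\].
#' @param b_L Lapse choice bias toward "stimulus 2 greater" in \[0, 1\].
#' @return An object of class `"percept_params"`.
#' @export
percept_params <- function(tau = 600, mu_b = 0, sigma2_b = 0,
                           p_L = 0, b_L = 0.5) {
  if (tau <= 0) stop("'tau' must be > 0")
  if (sigma2_b < 0) stop("'sigma2_b' must be >= 0")
  if (p_L < 0 || p_L > 1) stop("'p_L' must be in [0, 1]")
  if (b_L < 0 || b_L > 1) stop("'b_L' must be in [0, 1]")
  structure(list(tau = tau, mu_b = mu_b, sigma2_b = sigma2_b,
                 p_L = p_L, b_L = b_L),
            class = "percept_params")
}

#' @export
print.percept_params <- function(x, ...) {
  cat(sprintf(
    "Percept parameters: tau = %.0f ms, mu_b = %.3g, sigma2_b = %.3g, p_L = %.3f, b_L = %.3f\n",
    x$tau, x$mu_b, x$sigma2_b, x$p_L, x$b_L))
  invisible(x)
}

#' Closed-form percept distribution at stimulus offset
#'
#' Because the drive is (conditionally) Poisson and the background Gaussian,
#' the integrator value at time `T` is Gaussian with moments
#' \deqn{E[\Upsilon(T)] = E[\Upsilon(0)]e^{-T/\tau} + \mu_b(1-e^{-T/\tau})
#'   + \int_0^T e^{-(T-t')/\tau} f(t')\,dt'}
#' \deqn{Var[\Upsilon(T)] = Var[\Upsilon(0)]e^{-2T/\tau}
#'   + \sigma^2_b(1-e^{-2T/\tau}) + \int_0^T e^{-2(T-t')/\tau} f(t')\,dt'}
#' where the Poisson drive contributes its rate to both moments. The
#' integrals are evaluated discretely on the 1-ms drive grid (midpoint rule).
#' The integrator is reset at each stimulus onset
#' (`y0_mean = y0_var = 0` by default).
#'
#' @param drive Mean summed population rate per 1-ms bin over the stimulus
#'   epoch (numeric vector in spikes/ms), or a `"population_drive"` whose
#'   `$rate` is used.
#' @param params A [percept_params()] object.
#' @param T Stimulus duration in ms; defaults to the drive length.
#' @param y0_mean,y0_var Moments of \eqn{\Upsilon(0)}.
#' @return An object of class `"percept_distribution"`: `mean`, `variance`,
#'   `duration_T`.
#' @export
integrate_percept <- function(drive, params, T = NULL,
                              y0_mean = 0, y0_var = 0) {
  if (inherits(drive, "population_drive")) drive <- drive$rate
  if (is.null(T)) T <- length(drive)
  if (length(drive) < T) stop("'drive' must be defined on [0, T]")
  f <- drive[seq_len(T)]
  # end-of-bin kernel: a spike landing in bin t decays over the remaining
  # T - t ms, matching the 1-ms Euler discretization of the integrator
  k1 <- exp(-(T - seq_len(T)) / params$tau)
  mean_y <- y0_mean * exp(-T / params$tau) +
    params$mu_b * (1 - exp(-T / params$tau)) +
    sum(k1 * f)
  var_y <- y0_var * exp(-2 * T / params$tau) +
    params$sigma2_b * (1 - exp(-2 * T / params$tau)) +
    sum(k1^2 * f)
  structure(list(mean = mean_y, variance = var_y, duration_T = T),
            class = "percept_distribution")
}

#' @export
print.percept_distribution <- function(x, ...) {
  cat(sprintf("Percept at T = %g ms: mean %.2f, variance %.2f\n",
              x$duration_T, x$mean, x$variance))
  invisible(x)
}

#' Monte-Carlo percept samples by Euler simulation
#'
#' Simulates the leaky-integrator stochastic differential equation directly:
#' per 1-ms step the integrator leaks by `dt/tau`, receives the Poisson
#' spike count of the bin, and receives a Gaussian background increment
#' whose moments are scaled so that the stationary background contribution
#' matches (`mu_b`, `sigma2_b`). This is the sampling counterpart of the
#' closed form in [integrate_percept()] and is used to cross-check it.
#'
#' @param drive Mean summed rate per 1-ms bin (spikes/ms); fresh Poisson
#'   counts are drawn per trial.
#' @param params A [percept_params()] object.
#' @param n_trials Number of simulated trials.
#' @param T Stimulus duration, ms.
#' @param rng_seed Seed.
#' @return Numeric vector of `n_trials` values of \eqn{\Upsilon(T)}.
#' @export
simulate_percept <- function(drive, params, n_trials = 1000L, T = NULL,
                             rng_seed = 1L) {
  if (inherits(drive, "population_drive")) drive <- drive$rate
  if (is.null(T)) T <- length(drive)
  f <- drive[seq_len(T)]
  dt <- 1
  decay <- 1 - dt / params$tau
  bg_mean <- params$mu_b / params$tau * dt
  bg_sd <- sqrt(2 * params$sigma2_b * dt / params$tau)
  withr_seed(rng_seed, {
    y <- numeric(n_trials)
    for (t in seq_len(T)) {
      k <- stats::rpois(n_trials, f[t])
      y <- y * decay + k + bg_mean + stats::rnorm(n_trials, 0, bg_sd)
    }
    y
  })
}

#' Probability of judging stimulus 2 longer
#'
#' Both percepts are Gaussian, so the attended-trial probability that
#' \eqn{\Upsilon(T_2) > \Upsilon(T_1)} is \eqn{1/2 + 1/2\,\mathrm{erf}(d')}
#' with
#' \eqn{d' = (E[\Upsilon(T_2)] - E[\Upsilon(T_1)]) /
#' \sqrt{2(Var[\Upsilon(T_1)] + Var[\Upsilon(T_2)])}}. Lapse trials respond
#' with bias `b_L`, giving
#' \deqn{P(T_2 > T_1) = p_L b_L + (1 - p_L)[1/2 + 1/2\,\mathrm{erf}(d')].}
#'
#' @param percept1,percept2 `"percept_distribution"` objects for stimulus 1
#'   and stimulus 2.
#' @param params A [percept_params()] (uses `p_L`, `b_L`).
#' @return Probability in \[0, 1\].
#' @export
choice_probability <- function(percept1, percept2, params) {
  v <- percept1$variance + percept2$variance
  if (v <= 0) stop("degenerate comparison: both percept variances are zero")
  dprime <- (percept2$mean - percept1$mean) / sqrt(2 * v)
  params$p_L * params$b_L +
    (1 - params$p_L) * (0.5 + 0.5 * erf(dprime))
}

#' Point where a choice curve crosses 50%
#'
#' Linear interpolation of the first upward 0.5-crossing of a monotone-ish
#' choice curve; used to read the PSE off predicted neurometric points.
#'
#' @param delta Stimulus difference axis (sorted).
#' @param p Choice probabilities at `delta`.
#' @return The interpolated crossing, or `NA` if the curve never crosses.
#' @export
curve_pse <- function(delta, p) {
  ord <- order(delta)
  delta <- delta[ord]; p <- p[ord]
  above <- p >= 0.5
  if (all(above) || all(!above)) return(NA_real_)
  i <- which(above)[1L]
  if (i == 1L) return(delta[1L])
  x0 <- delta[i - 1L]; x1 <- delta[i]
  y0 <- p[i - 1L]; y1 <- p[i]
  x0 + (0.5 - y0) * (x1 - x0) / (y1 - y0)
}
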