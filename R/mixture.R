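#' Variational Bayesian Gaussian mixture over neuron parameters
#'
#' Learns a mixture of `G` multivariate Gaussian classes over the 8 free
#' LNP parameters (I0, I1_ss, I1_peak, I2_ss, I2_peak, I3_peak, lambda_max,
#' upsilon), with class membership governed by a Dirichlet weight prior of
#' concentration `alpha`. A very small `alpha` (default 1e-6) emulates a
#' truncated Dirichlet process: the posterior concentrates weight on as many
#' classes as the data support, while `G` caps the granularity (default 5).
#' Classes whose posterior weight is negligible are retained and reported.
#'
#' Inference is standard mean-field variational Bayes with conjugate
#' Gaussian-Wishart priors on each class's mean and precision, initialized
#' from k-means and iterated to convergence of the responsibilities. The
#' decay time constants and onset times are excluded from the mixture space:
#' they vary little across neurons and are treated as population constants.
#'
#' @param param_vectors Numeric matrix (neurons x 8) or a list of
#'   [neuron_params()] / `"lnp_fit"` objects, from which the 8 free
#'   parameters are extracted.
#' @param G Maximum number of mixture classes.
#' @param alpha Dirichlet concentration parameter.
#' @param max_iter,tol Variational iteration controls.
#' @param rng_seed Seed for the k-means initialization.
#' @param taus Fixed decay time constants (ms) attached to sampled neurons.
#' @return An object of class `"neuron_mixture"`: `$weights` (length `G`,
#'   sums to 1), `$means` (`G` x 8), `$covariances` (8 x 8 x `G`),
#'   `$responsibilities`, `$assignments` (MAP class per neuron), `$alpha`,
#'   `$G`, `$iterations`, `$converged`, `$taus`.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(200, 0), 25), matrix(rnorm(200, 4), 25))
#' colnames(X) <- c("I0","I1_ss","I1_peak","I2_ss","I2_peak","I3_peak",
#'                  "lambda_max","upsilon")
#' fit <- fit_neuron_mixture(X, G = 5)
#' sort(fit$weights, decreasing = TRUE)[1:2]   # two dominant classes
#' @export
fit_neuron_mixture <- function(param_vectors, G = 5L, alpha = 1e-6,
                               max_iter = 300L, tol = 1e-7, rng_seed = 1L,
                               taus = c(tau_M = 48, tau_O = 49, tau_I = 28)) {
  X <- as_param_matrix(param_vectors)
  n <- nrow(X); d <- ncol(X)
  if (n < G + 1)
    stop(sprintf("need at least G + 1 = %d parameter vectors (got %d); use a smaller G",
                 G + 1, n))

  # conjugate prior hyperparameters
  alpha0 <- alpha
  beta0 <- 1
  m0 <- colMeans(X)
  nu0 <- d + 2
  # prior scale matrix: a down-weighted pooled covariance, so that the
  # posterior covariance of an occupied class is dominated by its data
  S_pool <- stats::cov(X) + diag(1e-6, d)
  W0_inv <- S_pool * 0.1
  W0 <- solve(W0_inv)

  # log of the Wishart normalizing constant B(W, nu)
  log_B <- function(W, nu) {
    ld <- determinant(W, logarithm = TRUE)$modulus
    -(nu / 2) * ld - (nu * d / 2) * log(2) -
      d * (d - 1) / 4 * log(pi) -
      sum(lgamma((nu + 1 - seq_len(d)) / 2))
  }

  vb_run <- function(r) {
    ak <- bk <- nuk <- numeric(G)
    mk <- matrix(0, G, d)
    Wk <- array(0, c(d, d, G))
    Nk <- xbar_k <- Sk <- NULL
    converged <- FALSE
    elbo <- -Inf
    it <- 0L
    for (it in seq_len(max_iter)) {
      # M-step: update posterior hyperparameters from responsibilities
      Nk <- colSums(r) + 1e-12
      xbar_k <- matrix(0, G, d)
      Sk <- array(0, c(d, d, G))
      for (g in seq_len(G)) {
        xbar_k[g, ] <- colSums(r[, g] * X) / Nk[g]
        Xc <- sweep(X, 2L, xbar_k[g, ])
        Sk[, , g] <- crossprod(Xc * sqrt(r[, g])) / Nk[g]
        ak[g] <- alpha0 + Nk[g]
        bk[g] <- beta0 + Nk[g]
        nuk[g] <- nu0 + Nk[g]
        mk[g, ] <- (beta0 * m0 + Nk[g] * xbar_k[g, ]) / bk[g]
        dm <- xbar_k[g, ] - m0
        Wk_inv <- W0_inv + Nk[g] * Sk[, , g] +
          (beta0 * Nk[g] / bk[g]) * tcrossprod(dm)
        Wk[, , g] <- solve(Wk_inv + diag(1e-10, d))
      }

      # E-step: expected log weights / log precisions -> responsibilities
      elog_pi <- digamma(ak) - digamma(sum(ak))
      elog_det <- vapply(seq_len(G), function(g)
        sum(digamma((nuk[g] + 1 - seq_len(d)) / 2)) + d * log(2) +
          as.numeric(determinant(Wk[, , g], logarithm = TRUE)$modulus),
        numeric(1L))
      log_rho <- matrix(0, n, G)
      for (g in seq_len(G)) {
        Xc <- sweep(X, 2L, mk[g, ])
        maha <- nuk[g] * rowSums((Xc %*% Wk[, , g]) * Xc) + d / bk[g]
        log_rho[, g] <- elog_pi[g] + 0.5 * elog_det[g] - 0.5 * maha -
          d / 2 * log(2 * pi)
      }
      log_rho <- log_rho - apply(log_rho, 1L, max)
      r_new <- exp(log_rho)
      r_new <- r_new / rowSums(r_new)
      delta <- mean(abs(r_new - r))
      r <- r_new
      if (delta < tol) { converged <- TRUE; break }
    }

    # variational lower bound (evidence bound) of the converged solution
    Nk <- colSums(r) + 1e-12
    elog_pi <- digamma(ak) - digamma(sum(ak))
    elog_det <- vapply(seq_len(G), function(g)
      sum(digamma((nuk[g] + 1 - seq_len(d)) / 2)) + d * log(2) +
        as.numeric(determinant(Wk[, , g], logarithm = TRUE)$modulus),
      numeric(1L))
    e_px <- e_pml <- e_qml <- 0
    for (g in seq_len(G)) {
      xbar <- colSums(r[, g] * X) / Nk[g]
      Xc <- sweep(X, 2L, xbar)
      Sg <- crossprod(Xc * sqrt(r[, g])) / Nk[g]
      dm1 <- xbar - mk[g, ]
      e_px <- e_px + 0.5 * Nk[g] *
        (elog_det[g] - d / bk[g] -
           nuk[g] * sum(Sg * Wk[, , g]) -
           nuk[g] * drop(dm1 %*% Wk[, , g] %*% dm1) -
           d * log(2 * pi))
      dm0 <- mk[g, ] - m0
      e_pml <- e_pml + 0.5 *
        (d * log(beta0 / (2 * pi)) + elog_det[g] - d * beta0 / bk[g] -
           beta0 * nuk[g] * drop(dm0 %*% Wk[, , g] %*% dm0)) +
        log_B(W0, nu0) + (nu0 - d - 1) / 2 * elog_det[g] -
        0.5 * nuk[g] * sum(W0_inv * Wk[, , g])
      h_lambda <- -log_B(Wk[, , g], nuk[g]) -
        (nuk[g] - d - 1) / 2 * elog_det[g] + nuk[g] * d / 2
      e_qml <- e_qml + 0.5 * elog_det[g] +
        d / 2 * log(bk[g] / (2 * pi)) - d / 2 - h_lambda
    }
    e_pz <- sum(r %*% elog_pi)
    e_ppi <- lgamma(G * alpha0) - G * lgamma(alpha0) +
      (alpha0 - 1) * sum(elog_pi)
    e_qz <- sum(r[r > 0] * log(r[r > 0]))
    e_qpi <- sum((ak - 1) * elog_pi) + lgamma(sum(ak)) - sum(lgamma(ak))
    elbo <- e_px + e_pz + e_ppi + e_pml - e_qz - e_qpi - e_qml

    # BIC of the posterior-mean mixture: used to pick among structured
    # initializations (occupied components only are counted as parameters)
    wts <- ak / sum(ak)
    occupied <- which(Nk > 0.5)
    dens <- matrix(0, n, length(occupied))
    for (j in seq_along(occupied)) {
      g <- occupied[j]
      Sig <- solve(Wk[, , g]) / max(nuk[g] - d - 1, 1e-6)
      Sig <- (Sig + t(Sig)) / 2
      ch <- chol(Sig + diag(1e-10, d))
      Xc <- sweep(X, 2L, mk[g, ])
      z <- backsolve(ch, t(Xc), transpose = TRUE)
      dens[, j] <- log(wts[g]) - sum(log(diag(ch))) -
        d / 2 * log(2 * pi) - 0.5 * colSums(z^2)
    }
    mx <- apply(dens, 1L, max)
    ll <- sum(mx + log(rowSums(exp(dens - mx))))
    k_par <- length(occupied) * (d + d * (d + 1) / 2) +
      (length(occupied) - 1)
    bic <- ll - k_par / 2 * log(n)

    list(r = r, ak = ak, bk = bk, nuk = nuk, mk = mk, Wk = Wk,
         elbo = elbo, bic = bic, converged = converged, iterations = it)
  }

  # structured initializations: k-means partitions into 1..G effective
  # classes, each embedded in the G-class model (unused classes start and
  # stay near-empty); the run with the best evidence bound wins
  seeds <- derive_seeds(rng_seed, G)
  runs <- lapply(seq_len(G), function(g_eff) {
    cl <- if (g_eff == 1L) rep(1L, n)
          else withr_seed(seeds[g_eff],
                          stats::kmeans(X, centers = g_eff, nstart = 5,
                                        iter.max = 50)$cluster)
    r0 <- matrix(1e-8, n, G)
    r0[cbind(seq_len(n), cl)] <- 1
    r0 <- r0 / rowSums(r0)
    vb_run(r0)
  })
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1L), "bic"))]]
  if (!best$converged)
    warning("variational mixture did not converge within 'max_iter'")
  r <- best$r; ak <- best$ak; bk <- best$bk
  nuk <- best$nuk; mk <- best$mk; Wk <- best$Wk
  it <- best$iterations

  weights <- ak / sum(ak)
  covs <- array(0, c(d, d, G),
                dimnames = list(colnames(X), colnames(X), NULL))
  for (g in seq_len(G)) {
    # posterior expected covariance under the inverse-Wishart
    covs[, , g] <- solve(Wk[, , g]) / max(nuk[g] - d - 1, 1e-6)
    covs[, , g] <- (covs[, , g] + t(covs[, , g])) / 2
  }
  dimnames(mk) <- list(NULL, colnames(X))

  structure(
    list(weights = weights, means = mk, covariances = covs,
         responsibilities = r,
         assignments = max.col(r),
         alpha = alpha, G = G, n = n, iterations = it,
         elbo = best$elbo, converged = best$converged, taus = taus),
    class = "neuron_mixture")
}

# Coerce fits / parameter lists / matrices to the (n x 8) mixture space.
as_param_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 8L) stop("parameter matrix must have 8 columns")
    if (is.null(colnames(x))) colnames(x) <- lnp_free_names
    return(x)
  }
  rows <- lapply(x, function(el) {
    p <- if (inherits(el, "lnp_fit")) el$params else el
    unlist(p[lnp_free_names])
  })
  do.call(rbind, rows)
}

#' @export
print.neuron_mixture <- function(x, ...) {
  cat(sprintf(
    "Variational Gaussian mixture over %d neurons: G = %d, alpha = %g (%s in %d iterations)\n",
    x$n, x$G, x$alpha,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("class weights:", paste(sprintf("%.3f", sort(x$weights, decreasing = TRUE)),
                              collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.neuron_mixture <- function(object, ...) {
  ord <- order(object$weights, decreasing = TRUE)
  out <- list(weights = object$weights[ord], means = object$means[ord, , drop = FALSE],
              occupancy = tabulate(object$assignments, object$G)[ord],
              G = object$G, n = object$n, converged = object$converged)
  class(out) <- "summary.neuron_mixture"
  out
}

#' @export
print.summary.neuron_mixture <- function(x, ...) {
  cat(sprintf("Mixture of %d classes over %d neurons\n", x$G, x$n))
  tab <- cbind(weight = round(x$weights, 4), n_assigned = x$occupancy,
               round(x$means, 3))
  print(tab)
  invisible(x)
}

#' Sample a surrogate vS1 population from a fitted mixture
#'
#' Draws `n` neurons: a class is drawn by posterior weight, an 8-vector from
#' that class's Gaussian, and the fixed time constants and onset times are
#' attached. Draws violating the positivity constraints on `lambda_max` and
#' `upsilon` are rejected and redrawn (the mixture space is kept Gaussian);
#' the rejection count is recorded in the `"n_rejected"` attribute.
#'
#' @param model A `"neuron_mixture"`.
#' @param n Population size (the full-scale surrogate uses 5000).
#' @param rng_seed Seed; a fixed seed reproduces the population.
#' @param t0_M,t0_O Onset times attached to every neuron, ms.
#' @return A list of `n` [neuron_params()] objects with attribute
#'   `n_rejected`.
#' @export
sample_population <- function(model, n = 5000L, rng_seed = 1L,
                              t0_M = 0, t0_O = 0) {
  stopifnot(inherits(model, "neuron_mixture"), n >= 1)
  d <- ncol(model$means)
  chols <- lapply(seq_len(model$G), function(g) {
    S <- model$covariances[, , g]
    chol(S + diag(1e-9 * max(diag(S), 1), d))
  })
  withr_seed(rng_seed, {
    out <- vector("list", n)
    n_rejected <- 0L
    for (i in seq_len(n)) {
      repeat {
        g <- sample.int(model$G, 1L, prob = model$weights)
        a <- model$means[g, ] + drop(stats::rnorm(d) %*% chols[[g]])
        if (a[["lambda_max"]] > 0 && a[["upsilon"]] > 0) break
        n_rejected <- n_rejected + 1L
      }
      out[[i]] <- neuron_params(
        I0 = a[["I0"]], I1_ss = a[["I1_ss"]], I1_peak = a[["I1_peak"]],
        I2_ss = a[["I2_ss"]], I2_peak = a[["I2_peak"]], I3_peak = a[["I3_peak"]],
        lambda_max = a[["lambda_max"]], upsilon = a[["upsilon"]],
        tau_M = model$taus[["tau_M"]], tau_O = model$taus[["tau_O"]],
        tau_I = model$taus[["tau_I"]], t0_M = t0_M, t0_O = t0_O)
    }
    attr(out, "n_rejected") <- n_rejected
    out
  })
}

#' Summed expected firing rate of a population
#'
#' @param population A list of [neuron_params()].
#' @param T Stimulus duration, ms.
#' @param light Optogenetic drive on/off.
#' @param t Time axis in ms (default `0:(T-1)`, the stimulus epoch).
#' @param intensity_gain Multiplier on mechanoreceptor currents.
#' @return Summed rate in spikes per 1-ms bin at each `t`.
#' @export
population_rate <- function(population, T, light = FALSE,
                            t = seq.int(0, T - 1), intensity_gain = 1) {
  rate <- numeric(length(t))
  for (p in population) {
    if (intensity_gain != 1) {
      p$I1_ss <- p$I1_ss * intensity_gain
      p$I1_peak <- p$I1_peak * intensity_gain
    }
    rate <- rate + lnp_rate(p, t, T, light = light)
  }
  rate
}

#' Summed population spiking: the drive to the percept model
#'
#' The drive is the 1-ms-binned spike count summed over the whole modeled
#' population. Because the neurons are conditionally independent Poisson
#' units, the summed count per bin is itself Poisson with mean equal to the
#' summed rate, which is how the draw is performed.
#'
#' @inheritParams population_rate
#' @param n_trials Number of independent trials to draw.
#' @param rng_seed Seed.
#' @return An object of class `"population_drive"`: `$counts`
#'   (n_trials x n_bins), `$rate` (expected summed rate per bin),
#'   `$time_ms`, `$condition`.
#' @export
population_drive <- function(population, T, light = FALSE, n_trials = 1L,
                             rng_seed = 1L, t = seq.int(0, T - 1),
                             intensity_gain = 1) {
  if (!length(population)) stop("'population' must be non-empty")
  rate <- population_rate(population, T, light, t, intensity_gain)
  counts <- withr_seed(rng_seed, matrix(
    stats::rpois(n_trials * length(t), rep(rate, each = n_trials)),
    nrow = n_trials))
  structure(
    list(counts = counts, rate = rate, time_ms = t, bin_width = 1,
         condition = list(T = T, light = light,
                          intensity_gain = intensity_gain)),
    class = "population_drive")
}

#' @export
print.population_drive <- function(x, ...) {
  cat(sprintf(
    "Population drive: %d trial%s x %d 1-ms bins (T = %g ms, light %s), mean %.1f spikes/ms\n",
    nrow(x$counts), if (nrow(x$counts) > 1) "s" else "", ncol(x$counts),
    x$condition$T, if (isTRUE(x$condition$light)) "on" else "off",
    mean(x$rate)))
  invisible(x)
}

#' Serialize a mixture model as JSON
#'
#' @param model A `"neuron_mixture"`.
#' @param path Output path.
#' @export
write_mixture_json <- function(model, path) {
  stopifnot(inherits(model, "neuron_mixture"))
  rec <- list(G = model$G, alpha = model$alpha,
              weights = model$weights,
              means = model$means,
              covariances = apply(model$covariances, 3L, identity,
                                  simplify = FALSE),
              taus = as.list(model$taus),
              param_names = colnames(model$means))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mixture_json
#' @export
read_mixture_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- length(rec$param_names)
  covs <- array(0, c(d, d, rec$G),
                dimnames = list(rec$param_names, rec$param_names, NULL))
  for (g in seq_len(rec$G)) {
    covs[, , g] <- if (is.list(rec$covariances) ||
                       length(dim(rec$covariances)) != 3L)
      matrix(unlist(rec$covariances[[g]]), d, d)
    else rec$covariances[g, , ]
  }
  means <- rec$means
  dimnames(means) <- list(NULL, rec$param_names)
  structure(
    list(weights = rec$weights, means = means, covariances = covs,
         responsibilities = NULL, assignments = NULL,
         alpha = rec$alpha, G = rec$G, n = NA_integer_,
         iterations = NA_integer_, converged = NA,
         taus = unlist(rec$taus)),
    class = "neuron_mixture")
}
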