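#' Build or read a choice table
#'
#' The behavioral unit of analysis: one row per stimulus-pair cell with the
#' normalized differences, light condition, trial count and the number of
#' trials on which stimulus 2 was judged greater.
#'
#' @param delta_T,delta_I Normalized differences of the cell.
#' @param light Light condition label.
#' @param n_trials,n_chose2 Trial count and "stimulus 2 greater" count.
#' @param congruence Optional congruence labels (computed from the deltas
#'   when omitted).
#' @return A data frame of class `"choice_table"`.
#' @export
choice_table <- function(delta_T, delta_I, n_trials, n_chose2,
                         light = "none", congruence = NULL) {
  if (any(n_chose2 < 0) || any(n_chose2 > n_trials))
    stop("'n_chose2' must lie in [0, n_trials]")
  if (is.null(congruence)) congruence <- congruence_label(delta_T, delta_I)
  out <- data.frame(delta_T = delta_T, delta_I = delta_I, light = light,
                    congruence = congruence,
                    n_trials = as.integer(n_trials),
                    n_chose2 = as.integer(n_chose2),
                    stringsAsFactors = FALSE)
  class(out) <- c("choice_table", "data.frame")
  out
}

#' Read / write choice tables as CSV
#'
#' Accepts either the aggregated per-cell layout (`n_trials`, `n_chose2`) or
#' a long per-trial layout (one row per trial with a 0/1 `chose2` column),
#' which is aggregated on read.
#'
#' @param path File path.
#' @param table A `"choice_table"`.
#' @export
read_choice_csv <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"light" %in% names(dat)) dat$light <- "none"
  if (all(c("n_trials", "n_chose2") %in% names(dat))) {
    return(choice_table(dat$delta_T, dat$delta_I, dat$n_trials,
                        dat$n_chose2, dat$light))
  }
  if (!"chose2" %in% names(dat))
    stop("CSV must have either (n_trials, n_chose2) or a per-trial 'chose2' column")
  agg <- stats::aggregate(cbind(n_chose2 = dat$chose2,
                                n_trials = rep(1L, nrow(dat))),
                          by = list(delta_T = dat$delta_T,
                                    delta_I = dat$delta_I,
                                    light = dat$light),
                          FUN = sum)
  choice_table(agg$delta_T, agg$delta_I, agg$n_trials, agg$n_chose2,
               agg$light)
}

#' @rdname read_choice_csv
#' @export
write_choice_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# Evaluate the 4-parameter logistic choice curve.
psychometric_curve <- function(delta, gamma, lambda_u, u, nu) {
  gamma + (1 - lambda_u - gamma) / (1 + exp(-(delta - u) / nu))
}

#' Fit a four-parameter logistic psychometric function
#'
#' Nonlinear least squares of
#' \deqn{P(\Delta) = \gamma + (1 - \lambda - \gamma)
#'   \frac{1}{1 + e^{-(\Delta - u)/\nu}}}
#' to the observed choice proportions along the relevant axis, weighted by
#' trial counts, with \eqn{\gamma, \lambda \in [0, 0.5]} and multi-start
#' bounded optimization. `gamma` is the lower asymptote, `lambda_u` the
#' upper-asymptote deficit, `u` the inflection point and `1/nu` the
#' (scaled) maximum slope.
#'
#' The PSE is the \eqn{\Delta} at which the *fitted* curve crosses 50%,
#' which differs from `u` when the asymptotes are asymmetric:
#' \eqn{PSE = u - \nu \log[(1-\lambda-\gamma)/(1/2-\gamma) - 1]}.
#'
#' @param table A `"choice_table"` (or data frame with the same columns).
#' @param axis `"duration"` (fit against `delta_T`) or `"intensity"`
#'   (`delta_I`).
#' @param n_starts Number of optimization starts.
#' @param rng_seed Seed for the start jitter.
#' @return An object of class `"psychometric_fit"`: `$par` (gamma,
#'   lambda_u, u, nu), `$pse`, `$slope` (= 1/nu), `$sse`, `$data`
#'   (aggregated proportions), `$degenerate` flag.
#' @examples
#' tb <- choice_table(delta_T = seq(-0.35, 0.35, length.out = 7), delta_I = 0,
#'                    n_trials = 200,
#'                    n_chose2 = c(8, 30, 70, 104, 140, 172, 190))
#' fit <- fit_psychometric(tb, "duration")
#' fit$pse
#' @export
fit_psychometric <- function(table, axis = c("duration", "intensity"),
                             n_starts = 5L, rng_seed = 1L) {
  axis <- match.arg(axis)
  delta_col <- if (axis == "duration") "delta_T" else "delta_I"
  agg <- stats::aggregate(
    cbind(n_chose2 = table$n_chose2, n_trials = table$n_trials),
    by = list(delta = table[[delta_col]]), FUN = sum)
  if (nrow(agg) < 4L)
    stop("need at least 4 distinct levels on the '", axis, "' axis")
  prop <- agg$n_chose2 / agg$n_trials
  w <- agg$n_trials / mean(agg$n_trials)
  degenerate <- all(prop <= 0) || all(prop >= 1)
  if (degenerate)
    warning("degenerate choice data (all 0 or all 1); boundary fit returned")

  span <- diff(range(agg$delta))
  sse <- function(th) {
    pr <- psychometric_curve(agg$delta, th[1L], th[2L], th[3L], th[4L])
    sum(w * (prop - pr)^2)
  }
  lower <- c(0, 0, min(agg$delta) - span, span / 200)
  upper <- c(0.5, 0.5, max(agg$delta) + span, span * 5)
  base_init <- c(0.05, 0.05, agg$delta[which.min(abs(prop - 0.5))],
                 span / 8)
  inits <- withr_seed(rng_seed, lapply(seq_len(n_starts), function(i) {
    if (i == 1L) base_init
    else pmin(pmax(base_init + stats::rnorm(4L, 0,
        c(0.05, 0.05, span / 6, span / 10)), lower + 1e-8), upper - 1e-8)
  }))
  fits <- lapply(inits, function(st) {
    try(stats::optim(st, sse, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 500)),
        silent = TRUE)
  })
  fits <- Filter(function(f) !inherits(f, "try-error"), fits)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
  par <- stats::setNames(best$par, c("gamma", "lambda_u", "u", "nu"))

  # PSE: delta where the fitted curve equals 0.5
  amp <- 1 - par["lambda_u"] - par["gamma"]
  pse <- if (par["gamma"] < 0.5 && 1 - par["lambda_u"] > 0.5)
    unname(par["u"] - par["nu"] * log(amp / (0.5 - par["gamma"]) - 1))
  else NA_real_

  structure(
    list(par = par, pse = pse, slope = unname(1 / par["nu"]),
         sse = best$value, axis = axis,
         data = data.frame(delta = agg$delta, n_trials = agg$n_trials,
                           n_chose2 = agg$n_chose2, prop = prop),
         degenerate = degenerate, convergence = best$convergence),
    class = "psychometric_fit")
}

#' @export
coef.psychometric_fit <- function(object, ...) object$par

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Psychometric fit (%s axis): PSE = %.4f, slope 1/nu = %.2f\n",
              x$axis, x$pse, x$slope))
  print(round(x$par, 4))
  invisible(x)
}

#' @export
predict.psychometric_fit <- function(object, delta = NULL, ...) {
  if (is.null(delta)) delta <- object$data$delta
  psychometric_curve(delta, object$par["gamma"], object$par["lambda_u"],
                     object$par["u"], object$par["nu"])
}

#' @export
plot.psychometric_fit <- function(x, ...) {
  grid <- seq(min(x$data$delta), max(x$data$delta), length.out = 200)
  plot(x$data$delta, 100 * x$data$prop,
       xlab = if (x$axis == "duration") expression(Delta * T)
              else expression(Delta * I),
       ylab = "choice: stimulus 2 greater (%)", ylim = c(0, 100), pch = 16,
       ...)
  graphics::lines(grid, 100 * predict(x, grid))
  graphics::abline(h = 50, v = x$pse, lty = 3)
  invisible(x)
}

#' Bootstrap resampling of a choice table
#'
#' Resamples trials with replacement within each cell (preserving the cell
#' sizes) and refits the psychometric function, yielding the (PSE, mean %
#' choice) clouds used for the SVM separation analysis and parameter CIs.
#'
#' @param table A `"choice_table"`.
#' @param axis Relevant axis passed to [fit_psychometric()].
#' @param n_boot Number of resamples (the reference analysis uses 1000).
#' @param rng_seed Seed.
#' @param exclude_easy Drop the easiest cells (relevant |delta| at the
#'   design extremes) from the mean-choice summary, per the bias analyses.
#' @return A data frame with one row per resample: the four fitted
#'   parameters, `pse` and `mean_choice` (the averaged percent judged
#'   "stimulus 2 greater", not involving the fit).
#' @export
bootstrap_psychometric <- function(table, axis = c("duration", "intensity"),
                                   n_boot = 1000L, rng_seed = 1L,
                                   exclude_easy = TRUE) {
  axis <- match.arg(axis)
  delta_col <- if (axis == "duration") "delta_T" else "delta_I"
  keep <- if (exclude_easy) !is_easy(table, axis) else rep(TRUE, nrow(table))
  p_hat <- table$n_chose2 / table$n_trials
  seeds <- derive_seeds(rng_seed, n_boot)
  rows <- lapply(seq_len(n_boot), function(b) {
    k <- withr_seed(seeds[b],
                    stats::rbinom(nrow(table), table$n_trials, p_hat))
    tb <- table; tb$n_chose2 <- k
    fit <- fit_psychometric(tb, axis, n_starts = 2L, rng_seed = seeds[b])
    c(fit$par, pse = fit$pse,
      mean_choice = 100 * mean(k[keep] / table$n_trials[keep]))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("gamma", "lambda_u", "u", "nu", "pse", "mean_choice")
  out
}

# Easy-trial mask: the relevant-feature difference sits at the design
# extremes (|dT| = 0.35, |dI| = 0.3), where the irrelevant feature cannot
# sway the choice.
is_easy <- function(table, relevant = c("duration", "intensity"),
                    easy_cut = NULL) {
  relevant <- match.arg(relevant)
  delta <- if (relevant == "duration") table$delta_T else table$delta_I
  if (is.null(easy_cut))
    easy_cut <- if (relevant == "duration") 0.345 else 0.295
  abs(delta) >= easy_cut
}

#' Bias of the irrelevant feature on choice
#'
#' Sorts trials by the irrelevant feature and, with the relevant values
#' pooled, averages the percent judged "stimulus 2 greater" at each
#' irrelevant-difference level — isolating, e.g., the effect of intensity on
#' perceived duration. Easy trials (relevant difference at the design
#' extremes) are excluded, and the result is normalized by subtracting the
#' value at the irrelevant difference of 0 (where no bias can act).
#'
#' @param table A `"choice_table"`.
#' @param relevant The task-relevant feature (`"duration"` or
#'   `"intensity"`); the bias is measured along the other axis.
#' @param normalize Subtract the irrelevant-delta-0 level.
#' @return A data frame `delta` (irrelevant level), `bias_percent`,
#'   `n_trials`.
#' @export
bias_measure <- function(table, relevant = c("duration", "intensity"),
                         normalize = TRUE) {
  relevant <- match.arg(relevant)
  irr_col <- if (relevant == "duration") "delta_I" else "delta_T"
  keep <- !is_easy(table, relevant)
  tb <- table[keep, , drop = FALSE]
  if (!nrow(tb)) stop("no trials left after excluding easy trials")
  agg <- stats::aggregate(
    cbind(pct = 100 * tb$n_chose2 / tb$n_trials, n = tb$n_trials),
    by = list(delta = round(tb[[irr_col]], 6)),
    FUN = mean)
  out <- data.frame(delta = agg$delta, bias_percent = agg$pct,
                    n_trials = agg$n)
  if (normalize) {
    zero <- which(abs(out$delta) < 1e-9)
    if (!length(zero)) {
      warning("no irrelevant delta = 0 level; normalization skipped")
    } else {
      out$bias_percent <- out$bias_percent - out$bias_percent[zero[1L]]
    }
  }
  out[order(out$delta), ]
}

#' Resampling test for a choice bias between two conditions
#'
#' Trials are resampled with replacement within each cell of both tables;
#' at every iteration the averaged percent "stimulus 2 greater" (easy trials
#' excluded) is differenced between the two conditions
#' (`bias = mean_A - mean_B`), and the p-value is the fraction of
#' iterations with `bias >= 0`. Small p therefore indicates that condition
#' A sits reliably below condition B.
#'
#' @param table_A,table_B `"choice_table"`s for the two conditions.
#' @param relevant Relevant feature, for the easy-trial exclusion.
#' @param n_iter Number of resampling iterations (default 1000).
#' @param rng_seed Seed.
#' @param delta_subset Optional subset of relevant-delta values to test on
#'   (e.g. only the delta = 0 pairs).
#' @return A list: `p_value`, `bias` (observed difference), `bias_resampled`
#'   (the iteration values).
#' @export
permutation_bias_test <- function(table_A, table_B,
                                  relevant = c("duration", "intensity"),
                                  n_iter = 1000L, rng_seed = 1L,
                                  delta_subset = NULL) {
  relevant <- match.arg(relevant)
  prep <- function(tb) {
    if (!is.null(delta_subset)) {
      dcol <- if (relevant == "duration") "delta_T" else "delta_I"
      tb <- tb[round(tb[[dcol]], 6) %in% round(delta_subset, 6), ,
               drop = FALSE]
    }
    tb <- tb[!is_easy(tb, relevant), , drop = FALSE]
    if (!nrow(tb)) stop("no trials left in one condition after exclusions")
    tb
  }
  A <- prep(table_A); B <- prep(table_B)
  mean_pct <- function(k, n) 100 * mean(k / n)
  bias_obs <- mean_pct(A$n_chose2, A$n_trials) -
    mean_pct(B$n_chose2, B$n_trials)
  pA <- A$n_chose2 / A$n_trials
  pB <- B$n_chose2 / B$n_trials
  bias_it <- withr_seed(rng_seed, vapply(seq_len(n_iter), function(i) {
    kA <- stats::rbinom(nrow(A), A$n_trials, pA)
    kB <- stats::rbinom(nrow(B), B$n_trials, pB)
    mean_pct(kA, A$n_trials) - mean_pct(kB, B$n_trials)
  }, numeric(1L)))
  list(p_value = sum(bias_it >= 0) / n_iter,
       bias = bias_obs, bias_resampled = bias_it)
}

#' SVM separation of two bootstrap clouds
#'
#' Quantifies the linear separability of two condition clouds in the
#' (PSE, mean % choice) plane with a linear support vector machine
#' (cost 1) and 10-fold cross-validation; the returned error is the
#' cross-validated misclassification rate (0.5 = chance, 0 = fully
#' separated).
#'
#' @param points_A,points_B Two-column matrices or data frames (typically
#'   `pse` and `mean_choice` from [bootstrap_psychometric()]).
#' @param n_folds Cross-validation folds.
#' @param rng_seed Seed controlling fold assignment.
#' @return A list: `error` (CV misclassification rate), `n_A`, `n_B`.
#' @export
svm_separation <- function(points_A, points_B, n_folds = 10L, rng_seed = 1L) {
  A <- as.matrix(points_A)[, 1:2, drop = FALSE]
  B <- as.matrix(points_B)[, 1:2, drop = FALSE]
  if (nrow(A) < 20L || nrow(B) < 20L)
    stop("need at least 20 points per cloud (bootstrap resamples)")
  X <- rbind(A, B)
  y <- factor(rep(c("A", "B"), c(nrow(A), nrow(B))))
  fit <- withr_seed(rng_seed,
    e1071::svm(X, y, kernel = "linear", cost = 1, scale = TRUE,
               cross = n_folds))
  list(error = 1 - fit$tot.accuracy / 100, n_A = nrow(A), n_B = nrow(B))
}

#' Accuracy on congruent versus incongruent trials
#'
#' Splits the table by the congruence of the irrelevant feature with the
#' relevant one and computes the percent-correct in each class (a choice is
#' correct when it follows the sign of the relevant difference). The spread
#' and the one-sided comparison come from trial-level bootstrap resampling.
#'
#' @param table A `"choice_table"` with congruence labels; rows with
#'   relevant delta = 0 are excluded (no correct answer).
#' @param relevant Relevant feature.
#' @param n_boot Bootstrap iterations for the spread and p-value.
#' @param rng_seed Seed.
#' @return A list: `accuracy` (named: congruent, incongruent, in %), `sd`
#'   (bootstrap STDs), `p_value` (one-sided, congruent <= incongruent under
#'   resampling).
#' @export
congruence_accuracy <- function(table, relevant = c("duration", "intensity"),
                                n_boot = 1000L, rng_seed = 1L) {
  relevant <- match.arg(relevant)
  delta <- if (relevant == "duration") table$delta_T else table$delta_I
  tb <- table[delta != 0 & table$congruence != "neutral", , drop = FALSE]
  if (!all(c("congruent", "incongruent") %in% tb$congruence))
    stop("both congruence classes must be present")
  delta <- if (relevant == "duration") tb$delta_T else tb$delta_I
  n_correct <- ifelse(delta > 0, tb$n_chose2, tb$n_trials - tb$n_chose2)
  acc <- function(k) vapply(c("congruent", "incongruent"), function(cl) {
    sel <- tb$congruence == cl
    100 * sum(k[sel]) / sum(tb$n_trials[sel])
  }, numeric(1L))
  observed <- acc(n_correct)
  p_corr <- n_correct / tb$n_trials
  boot <- withr_seed(rng_seed, vapply(seq_len(n_boot), function(i) {
    acc(stats::rbinom(nrow(tb), tb$n_trials, p_corr))
  }, numeric(2L)))
  list(accuracy = observed,
       sd = apply(boot, 1L, stats::sd),
       p_value = mean(boot["congruent", ] <= boot["incongruent", ]))
}
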