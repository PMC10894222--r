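# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}

# Logistic function; arguments in ms wherever it gates time.
expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

# Gauss error function via the normal CDF.
erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

# Derive a stream of sub-seeds from one master seed (keeps them < 2^31).
derive_seeds <- function(seed, n) {
  withr_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
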