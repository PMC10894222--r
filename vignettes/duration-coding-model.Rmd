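---
title: "Modeling tactile duration perception from cortical spiking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tactile duration perception from cortical spiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`vibratime` implements a chain of models linking whisker vibration stimuli
to trial-by-trial duration judgments: stimulus construction, a
linear–nonlinear–Poisson (LNP) description of single vS1 neurons under
sensory and optogenetic drive, a mixture model that scales a handful of
fitted neurons up to a surrogate population, a stochastic leaky integrator
that reads the summed population spiking out as perceived elapsed time,
and the psychophysical analyses applied to the resulting choices. This
vignette explains each model, its assumptions, the numerical choices made
in the implementation, and what the synthetic-data tests do and do not
establish.

## Stimuli and trial design

A vibration is a sequence of independent zero-mean Gaussian plate
velocities delivered at 1 kHz for `T` ms. Its perceptually relevant
intensity is the mean absolute speed, which for a Gaussian process of
standard deviation σ is `I = σ√(2/π)`; the package labels stimuli by this
nominal intensity rather than the per-trace empirical mean, because many
resampled traces share one nominal level. Trials pair a reference stimulus
(334 ms, 64 mm/s) with a comparison whose duration and intensity each take
seven log-spaced levels spanning 161–694 ms and 34–119 mm/s; only the
extremes and the reference are canonical, so intermediate levels are a
geometric series rounded to whole ms and mm/s. Rounding matters in one
place: the rounded middle intensity level equals the 64 mm/s reference, so
the irrelevant-feature bias analysis has an exact ΔI = 0 level to
normalize against. The reference intensity is quoted inconsistently in the
source material (64 vs 65 mm/s); 64 is the default and both are accepted
as arguments.

Trials are `congruent` when the duration and intensity differences share a
sign, `incongruent` when they conflict, `neutral` when either is zero —
the labeling is invariant under simultaneously swapping the two stimuli.

## The LNP neuron

The firing rate of unit *i* is built from three currents (arbitrary
units): a constant background `I0`; a mechanoreceptor current that jumps
to `I1_peak` at stimulus onset and decays to `I1_ss` with time constant
`tau_M` = 48 ms, gated by a logistic window
`expit(t − t0) · expit(−(t − T − t0))` with a ~1 ms shoulder; and an
optogenetic current of the same form (`I2_peak`, `I2_ss`, `tau_O` = 49 ms)
plus a post-light-offset current `I3_peak · exp(−(t − T − t0)/tau_I)`
(`tau_I` = 28 ms) that is allowed to be negative to express
post-stimulation suppression. The total current passes through a
generalized sigmoid

> rate = λ · [1 − (1 + e^{10·I})^{−1/υ}] + 10⁻⁴  (spikes per 1-ms bin)

and spikes are independent Poisson counts per 1-ms bin. The current scale
factor 10 and the 10⁻⁴ floor are fixed constants that stabilize fits of
low-firing neurons. All `expit` arguments are in ms. The three decay
constants vary little across neurons and are treated as population
constants at the values above; onset times `t0_M`, `t0_O` are set by the
experimental protocol (default 0; the photoinhibition protocol's 50 ms
early light onset is expressible through `light_t0`/`light_T`).

`fit_lnp` maximizes the Poisson likelihood of 10-ms-binned PSTH counts
(the 1-ms model rate is integrated across each bin) over the 8 free
parameters, with currents bounded to ±5 a.u., λ and υ optimized on the log
scale, a small ridge (10⁻³) on the currents, and multi-start L-BFGS-B.
`I0` is initialized by inverting the sigmoid at the pre-stimulus mean
rate. When only light-off PSTHs are supplied the four optogenetic currents
are unidentifiable and are frozen at zero. Non-convergence is warned, and
the best candidate returned with its per-start bookkeeping.

**Identifiability.** The nonlinearity scale υ trades off against the
currents on a nearly flat likelihood ridge when the data probe only one or
two operating points of the I/F curve: fits from two light levels alone
can land far from the generating υ while *exceeding* it in likelihood.
The parameter-recovery harness therefore fits jointly across four
mechanoreceptor gain levels (0.3–1.5× — the analogue of a multi-intensity
stimulus set) crossed with light on/off, 200 trials per condition, which
pins every free parameter in the recovery tests. Users fitting real PSTHs
should likewise include as many stimulus levels as available; with few
levels, υ estimates should be treated as nuisance quantities.

## The population mixture

Fitted 8-parameter vectors (`I0, I1_ss, I1_peak, I2_ss, I2_peak, I3_peak,
λ, υ`) are modeled as a mixture of at most G = 5 multivariate Gaussian
classes with a Dirichlet weight prior of concentration α = 10⁻⁶; the tiny
concentration emulates a truncated Dirichlet process in which the data
decide how many classes carry weight, while G caps granularity. Inference
is mean-field variational Bayes with conjugate Gaussian–Wishart priors.
Two numerical choices matter:

- the Wishart prior scale is a *down-weighted* (0.1×) pooled covariance.
  A full-strength pooled-covariance prior inflates the posterior
  covariance of tight classes severely enough to obscure genuinely
  separated clusters.
- variational updates converge to whichever class structure they are
  started from, so the fit is run from structured initializations
  (k-means partitions into 1…G effective classes) and the winner is
  chosen by the BIC of the posterior-mean mixture. The variational bound
  itself proved too blunt an arbiter between merge/split solutions at
  realistic sample sizes; BIC is standard, and the choice is
  cross-checked against an independent EM clustering (`mclust`) in the
  test suite.

`sample_population` draws neurons class-by-weight and vector-by-class,
attaches the fixed time constants, and enforces λ, υ > 0 by rejection
(the mixture space stays Gaussian, faithful to the model; the rejection
count is logged so heavy truncation is visible). Summed population
spiking is drawn per 1-ms bin as Poisson of the summed rate — exact, since
independent Poisson units sum to a Poisson count.

## The percept model

Perceived elapsed time integrates the drive with leak:
dϒ/dt = −ϒ/τ + f(t), where f is the summed vS1 spiking plus ongoing
background input. ϒ(T) is Gaussian with

- E[ϒ(T)] = E[ϒ(0)]e^{−T/τ} + μ_b(1 − e^{−T/τ}) + Σ_t e^{−(T−t)/τ} f(t)
- Var[ϒ(T)] = Var[ϒ(0)]e^{−2T/τ} + σ²_b(1 − e^{−2T/τ}) + Σ_t e^{−2(T−t)/τ} f(t)

with the Poisson drive contributing its rate to both moments (the
integration variable runs over the drive, i.e. f(t′) inside the
integral). μ_b and σ²_b are parameterized as the *steady-state* background
contributions, matching the printed moment formulas; the Euler simulation
(`simulate_percept`) injects `(μ_b/τ)dt` and variance `2σ²_b dt/τ` per
step so both routes agree exactly, and the discrete kernel is end-of-bin
(`e^{−(T−t)/τ}`, t = 1…T) for the same reason — a midpoint kernel leaves a
systematic ~0.1% offset that a 10⁴-trial Monte-Carlo comparison resolves.
ϒ resets to 0 (zero variance) at each stimulus onset: the inter-stimulus
delay is unmodeled and only ϒ at each stimulus's offset enters the
comparison.

Choices follow P(T₂>T₁) = p_L·b_L + (1−p_L)[½ + ½·erf(d′)] with
d′ = (E₂−E₁)/√(2(V₁+V₂)); a comparison with zero total variance is an
error, not a limit. `fit_percept` maximizes the per-condition binomial
likelihood over (log τ, μ_b, log σ²_b, logit p_L, logit b_L) with the L2
penalty `0.01·((τ − 600)/600)²` — the penalty's weight and center are
canonical, its normalization (by the center, making the weight
dimensionless) is this package's choice and both are arguments. The
likelihood sums over all supplied population proxies, fitting one common
parameter set.

**Identifiability.** With choice data from a single drive regime, τ trades
against (μ_b, σ²_b) on a flat ridge: fits hundreds of ms from the
generating τ can win by fractions of a nat at 10⁴ trials. Sessions that
include photoexcitation of stimulus 1 and of stimulus 2 provide three
drive regimes and restore identifiability; the recovery harness uses that
design. Fits to light-off-only data should report τ with the penalty
acknowledged as informative.

## Psychophysics

The psychometric curve is the 4-parameter logistic
P(Δ) = γ + (1−λ−γ)/(1 + e^{−(Δ−u)/ν}) fitted by trial-weighted least
squares with γ, λ ∈ [0, 0.5] and multi-start bounded optimization. The
PSE is where the *fitted* curve crosses 50% — with asymmetric lapses this
differs from u — and the slope is reported as 1/ν. All-0 or all-1 data
yield a flagged boundary fit. Bias of the irrelevant feature: easy trials
(relevant |Δ| at the design extremes) are excluded, the percent judged
"stimulus 2 greater" is averaged per irrelevant level, and the ΔI = 0
level is subtracted (skipped with a warning if absent). The
condition-difference test resamples trials with replacement within cells
(binomial resampling of each cell), differencing the averaged percentages
per iteration; p = (#iterations with bias ≥ 0)/n. Trial-level rather than
session-level resampling is a documented choice. SVM separation of
bootstrap (PSE, mean % choice) clouds uses a linear kernel, cost 1 and
10-fold cross-validation. Congruence accuracy counts a choice correct
when it follows the sign of the relevant difference, and compares classes
by bootstrap.

## Spike-train metrics

Rates are estimated in 1-ms steps with a centered 40-ms sliding window.
Z-scoring subtracts the baseline mean (−800–0 ms) and divides by the
baseline *variance* — literally the stated normalization — with
`divisor = "sd"` available for the conventional z-score; zero-variance
baselines flag the neuron for exclusion. Population PSTHs are smoothed
with a half-Gaussian (σ = 25 ms) whose tail flips at the trace midpoint:
ahead of the flip the kernel averages only earlier samples, after it only
later ones, so smoothing cannot move response mass across the stimulus
onset or offset; for pooling across durations the first 150 ms and final
50 ms can be concatenated. Onset/offset detection thresholds the smoothed
rate at baseline mean + 2.2 STD (baseline −480 to −20 ms), interpolates
crossings linearly between 1-ms samples, and takes the crossings bounding
the *longest* suprathreshold epoch — a literal first/last-crossing rule
mistakes stray baseline noise excursions for boundaries whenever the
trace extends well past the stimulus. Detections more than 25 ms from the
true boundaries are invalidated as outliers. Intensity coding is a
two-sided shuffle test (1000 label shuffles, α = 0.05) on the correlation
between whole-stimulus mean rate and intensity (the rate window is not
canonical; whole-stimulus is the choice here), and population clouds are
resampled at a 90/10 coding/non-coding composition.

## The synthetic-data generators

`synthetic_observer` emulates a behaving rat: constant summed drive
(default 2 spikes/ms, the scale of a few hundred low-rate cortical units)
integrated by a leaky integrator with τ = 500 ms, a 10% lapse rate with
unbiased lapses, an optional intensity-to-drive coupling
(`1 + c·(I/64 − 1)`) — the package's mechanism for intensity biasing
perceived duration — and a ×1.3 drive boost for a photoexcited stimulus.
`make_raster_set` generates labeled rasters from any neuron population
under duration × light × gain conditions. Everything is deterministic
under a recorded seed and serializable to a ground-truth JSON record whose
regeneration is bit-identical.

What the generators emulate: the trial design and its easy extremes,
lapse-contaminated choices, Poisson spiking with onset adaptation,
optogenetic rate boosts, and the intensity–duration coupling. What they
do not: session drift and reference-memory criterion setting, per-animal
idiosyncrasies, correlated (non-Poisson) population noise, reaction
times, and the working-memory asymmetry between the two stimulus
intervals. Passing recovery tests therefore establishes that the
estimators are correct and calibrated under the stated model, not that
the model captures every property of recorded rats.

## Scale of the shipped experiments

Tests and the acceptance script run at desk scale, chosen as the sizes at
which each check is already decisive: 10⁵ samples for the half-normal
identity (2%), 10⁴ trials for Poisson and moment-matching checks (3 SE),
200 trials/condition across eight conditions for LNP recovery, 120
two-cluster neurons for mixture recovery (the boundary where BIC reliably
detects full-covariance 8-D structure lies near 60), 10⁴ behavioral
trials across three light regimes for percept recovery, and 200 null
repetitions for the resampling-test calibration. The full-scale
configuration (5000 neurons, 100 proxies) is available via
`default_config(full_scale = TRUE)`.

## Known limitations

- υ and τ are identifiable only with multi-regime data (above); the
  package warns through documentation, not runtime heuristics.
- The mixture's rejection sampling biases sampled means when a class puts
  substantial mass at λ ≤ 0 or υ ≤ 0; the logged rejection count should
  be checked before trusting population summaries.
- The inhibition protocol's ramped light offset is representable only as
  a shifted/shortened light window, not a graded ramp.
- Percept-model fits inherit the τ regularization; reported τ near
  600 ms with weakly informative data reflects the penalty center.
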