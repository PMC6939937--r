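---
title: "Adaptive Bayesian estimation of stereoacuity thresholds: models, procedures and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Bayesian estimation of stereoacuity thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zestsim)
```

## The measurement problem

Stereoacuity is the smallest binocular disparity an observer can use to
detect depth. It is measured with forced-choice trials: a target at some
disparity appears in one of two (2AFC) or four (4AFC) locations, and the
observer picks a location. The probability of a correct response rises
from the guess rate $\gamma = 1/m$ ($m$ alternatives) toward
$1 - \lambda$, where $\lambda$ is the lapse rate — the probability of an
incorrect response caused by inattention rather than by the stimulus.
zestsim models this with a logistic psychometric function in
$x = \log_{10}(\text{disparity in arcsec})$:

$$\Psi(x) = \gamma + (1 - \gamma - \lambda)\,
  \frac{1}{1 + e^{-\beta (x - \alpha)}}.$$

The *threshold* $\theta$ is the intensity where $\Psi(\theta) = \pi$,
with criterion $\pi = 0.75$ throughout. The *spread* $\sigma$ is the
intensity interval over which the base logistic rises through its
central 95% (0.025 to 0.975), which fixes
$\beta\sigma = 2\ln 39 \approx 7.327$: a spread of 1 log unit means the
function rises over a factor of 10 in disparity. A useful companion
quantity is $\lambda^\* = \lambda / (1-\gamma)$, the probability of
lapsing at all — a lapse only produces an *incorrect* response with
probability $1 - \gamma$, so the same inattentiveness yields larger
$\lambda$ in 4AFC than in 2AFC.

All arithmetic is carried out in log10 arcsec; linear arcsec appears
only at I/O boundaries. Threshold estimates convert multiplicatively:
a mean log-bias $b$ means thresholds are off by a factor
`bias_factor(b)` $= 10^b$.

## Data collection: the weighted up/down staircase

Empirical sessions use a weighted one-up/one-down staircase
(`run_updown()`): start at 3 log10 arcsec (1000 arcsec), subtract
0.15 after a correct response, add 0.45 after an error, for a fixed 80
(or 120) trials. The unequal steps make the staircase equilibrate where
$p \cdot 0.15 = (1-p)\cdot 0.45$, i.e. at $p = 0.75$
(`equilibrium_probability()`), the same criterion at which thresholds
are defined. Trial 1 is a cued practice trial: the target carries a
non-stereo cue, so in simulation the observer answers it correctly with
probability at least 0.95, and it is flagged `practice` and excluded
from fits by default. Levels are clamped to $[0, 3]$ log10 arcsec
without reflection — the display cannot exceed the 1000-arcsec start
level, and thresholds of interest lie well inside.

## Fitting sessions

`fit_ml()` fits $(\theta, \sigma, \lambda)$ by maximum likelihood with
$\gamma$ fixed by the task, under the constraints $\sigma > 0$ and
$0 < \lambda < 0.06$. The function is parameterized by the threshold at
$\pi = 0.75$ directly, so the reported `theta_hat` needs no conversion.
The optimizer is the Nelder–Mead simplex (`stats::optim()`), run on
transformed coordinates — $\log\sigma$ and a logit-scaled $\lambda$ — so
the constraints hold by construction and the surface stays smooth; a
lattice of 24 starting points (4 threshold quantiles × 2 spreads ×
3 lapses) guards against local minima, and the best final likelihood
wins. A penalty path (large finite values outside the constraints)
exists only so that probe evaluations never throw.

Goodness of fit uses the deviance — twice the log-likelihood ratio of
the saturated model to the fit, with $0\ln 0 = 0$ — and a Monte-Carlo
p-value: `p_deviance()` simulates B = 1000 datasets from the fitted
probabilities at the same design and reports the fraction of simulated
deviances at least as large as the observed one, without refitting.
A parametric bootstrap was chosen because the per-level counts from a
staircase are small and unbalanced, which makes the asymptotic
chi-square reference unreliable. A fit is retained
(`passes_inclusion()`) when $\theta \in [1, 500]$ arcsec,
$\sigma \in [0.01, 7]$ and $p(\mathrm{Dev}) > 0.05$.

## Bayesian adaptive procedures

All seven procedures share one engine: a discrete hypothesis grid, Bayes
updates after every trial, and per-trial estimates from the posterior.

* **ZEST with fixed spread** (`zest_fixed_sigma`): posterior over the
  threshold only; the model function fixes the assumed spread
  $\sigma_M$ and lapse $\lambda_M$. Each trial is placed at the
  posterior mean (snapped to the nearest stimulus candidate, ties to
  the lower one) and the estimate is the posterior mean. The threshold
  prior is uniform — with a uniform prior the posterior *mode* is
  exactly the grid maximum-likelihood estimate, which the tests verify
  trial-for-trial against an exhaustive likelihood scan.
* **Two-dimensional ZEST** (`zest2d_theta_sigma`, `zest2d_theta`): a
  joint posterior over threshold and spread, with posterior-mean
  placement on the threshold marginal. The two variants differ only in
  reporting: one also returns a spread estimate, the other treats the
  spread purely as a nuisance parameter.
* **Psi** (`psi_theta_sigma`) and **Psi-marginal**
  (`psi_marg_theta_sigma_L`, `psi_marg_theta_SL`, `psi_marg_theta_S`):
  each trial is placed at the stimulus minimizing the expected Shannon
  entropy (bits, $0\log 0 = 0$) of the posterior marginalized onto the
  *interest* axes — all axes for Psi; threshold (and optionally spread)
  for the marginal variants, which treat the rest (spread and/or a
  lapse axis with a uniform prior) as nuisance. Entropy ties are broken
  toward the smaller intensity, deterministically.

Default grids: threshold axis $[0, 3]$ in steps of 0.01 with stimulus
candidates equal to the axis; a lapse axis $0, 0.01, \ldots, 0.06$
where a procedure marginalizes the lapse (covering the fitting
constraint $0 < \lambda < 0.06$); and a spread axis of 21 linearly
spaced values over $[0.01, 7]$ — the same range within which fitted
spreads are considered valid. Spread priors are uniform over the axis
or a Gaussian density evaluated at the axis values and renormalized;
threshold priors are always uniform.

### Grid parameterization: a reconstruction choice that matters

Two conventions exist for what a grid point *means*. Under the
`"threshold"` parameterization every hypothesis is located so that
$\Psi(\theta) = \pi$ exactly — the axis value *is* the threshold. Under
the `"location"` parameterization (the convention of the published Psi
family) the axis value is the location $\alpha$ of the base logistic,
and the threshold of a hypothesis is
$\theta = \alpha + \ln\!\big(F/(1-F)\big)/\beta$ with
$F = (\pi - \gamma)/(1 - \gamma - \lambda)$. The offset is
$0.112\,\sigma$ for 4AFC but only $0.011\,\sigma$ for 2AFC at
$\pi = 0.75$.

This is not a cosmetic difference. Under the location parameterization,
while the spread posterior is still broad — which it is for tens of
trials, since slope information accrues slowly — the threshold estimate
$E[\alpha] + 0.112\,E[\sigma]$ inherits the unresolved spread mass, and
with a wide spread prior this produces a systematic *overestimation* of
4AFC thresholds at small trial counts that is nearly absent in 2AFC.
Under the threshold parameterization the data pin the threshold
directly and no such bias appears. Because the entropy-minimizing Psi
procedures spend trials disambiguating the spread (and so resolve it
even more slowly than posterior-mean placement does), they show this
small-sample bias most strongly, with the two-dimensional ZEST largely
immune — exactly the qualitative ranking the procedure-comparison
simulations produce. zestsim therefore defaults to `"location"` for the
Psi family and `"threshold"` for the ZEST family (for fixed-spread ZEST
the two differ only by a constant shift and are equivalent); both are
available via `grid_parameterization=` in `procedure_config()`.

### Numerical choices

Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ before any
logarithm; posterior mass is renormalized after every update and checked
to $10^{-9}$ in the tests. The expected entropy is computed without
per-trial logarithms over the grid by the decomposition
$\sum_i w_i \log w_i = \sum_i p_i L_i(\log p_i + \log L_i)$ with the
$L\log L$ tables precomputed once per configuration; an independent
brute-force oracle (explicit enumeration of both responses and direct
marginalization) verifies the optimized path to $10^{-10}$ on grids up
to $10 \times 10 \times 5$. Monte-Carlo engines run all simulations of
a cell simultaneously as matrix operations (one posterior column per
run); with a single run this consumes the random stream in the same
order as `run_procedure()`, so the two paths coincide exactly under a
common seed, which is also tested.

## Virtual observers

`builtin_profile()` carries the population statistics of three
experiments (2AFC global, 4AFC global, 4AFC local stereopsis): means
and SDs of log thresholds, spreads and $\lambda^\*$, plus — for the
4AFC experiments, where spread and threshold correlate — a
spread-on-threshold regression. `sample_population()` draws observers
from truncated normals on the ranges $\theta \in [0, \log_{10}500]$,
$\sigma \in [0.01, 7]$, $\lambda^\* \in [0, 0.08]$.

Truncating a normal *shifts its moments*, so the parent parameters are
solved numerically until the post-truncation mean and SD equal the
published values; for the regression-coupled profiles the published
slope is kept and the intercept and residual SD are calibrated against
the truncated marginal. One published value is unattainable: the
$\lambda^\*$ SDs (≈ 0.04) exceed the maximum SD any distribution on
$[0, 0.08]$ with the published mean can have (Bhatia–Davis bound
≈ 0.035), reflecting the strongly non-normal, outlier-heavy empirical
lapse distributions; the sampler matches the mean exactly and gets as
close to the SD as the range permits (≈ 0.02). Lapse rates are always
derived from $\lambda^\*$ through the task's guess rate, so the
$\lambda = \lambda^\*(1-\gamma)$ identity is exact by construction.

What the generator emulates: the marginal moments, the valid parameter
ranges, and the 4AFC threshold–spread coupling. What it does not:
the multimodality and heavy tails of real spread and lapse
distributions, test–retest variability, observers that drift within a
session, or spatial response biases. Tests that pass on these
populations therefore certify the estimation machinery under idealized
stationary observers, not performance on any individual real subject.

## The percentile sweep and the |bias × SD| criterion

Fixed-spread ZEST needs an assumed spread $\sigma_M$. Fixing it wrong
biases thresholds, and asymmetrically so: overestimating the slope
(too-small $\sigma_M$) hurts much more than underestimating it, with
the small-$\sigma_M$ bias positive in 2AFC and negative in 4AFC.
`percentile_sweep()` chooses $\sigma_M$ for a *population*: candidate
values are the 5th–95th percentiles (steps of 5, linear-interpolation
quantiles) of the population's spreads; each candidate is evaluated by
Monte-Carlo (`bias_for_spread()`: per observer, the mean final-trial
bias over simulated 30-trial staircases; the summary averages observer
means unweighted, with the SD taken over the pooled per-run biases —
per-observer values are retained in an attribute since the pooling
convention is a choice); the optimum minimizes
$|\text{mean bias} \times \text{SD}|$, ties toward the smaller spread.
On populations drawn from the 2AFC-global profile the optimum lands at
the 80th percentile ($\sigma_M \approx 1.7$) across seeds, and the
test suite asserts the 55–85 band at a scaled-down 200 simulations
per cell. The model lapse can either copy each observer
(`lapse_mode = "subject"`) or stay fixed (`"fixed"`), since both
conditions are of interest and their optima barely differ.

## Problem sizes

The simulation sizes used by the tests and the results script are
the package's own defaults for desk-scale verification: 1000 runs for
the single-observer procedure benchmarks, 500 runs per point for the
mismatch-asymmetry surfaces, 200 simulations per cell for the
percentile sweep (19 percentiles × 71 observers), 200 replicates for
fit-recovery and bootstrap-calibration checks. Full-scale studies
(2000 simulations per cell, 142 000 staircases per percentile point)
run with the same functions by raising `n_sims`.

## Known limitations

* The benchmark simulations show a small residual positive bias
  (≈ +0.005 log units) for fixed-spread ZEST with $\sigma_M > \sigma_S$
  on the standard 4AFC observer; its sign and magnitude at this scale
  depend on grid and start-level details for which no published
  reference exists.
* Reported across-run SDs of adaptive threshold estimates at 20–30
  trials are of order 0.1 log units, consistent with the Fisher
  information available from ~25 forced-choice trials; across-subject
  SDs of per-subject mean bias are an order of magnitude smaller and
  should not be confused with them.
* The Psi-family overestimation magnitude depends on the spread-prior
  range and spacing; the defaults reproduce the phenomenon's direction,
  task-dependence and approximate size, but exact published magnitudes
  depend on implementation details of the original configurations.
* `fit_ml()` reports no confidence intervals; the deviance p-value is
  Monte-Carlo and therefore seed-dependent at the third decimal.
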