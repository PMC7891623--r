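---
title: "Continuous test norming with Bayesian distributional regression: models, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous test norming with Bayesian distributional regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdrnorm)
```

## The problem

A normed score expresses a raw test score relative to a reference
population that usually depends on age: the same raw score can be average
for an eight-year-old and far below average for a fifteen-year-old.
Continuous norming estimates the conditional score distribution as a
*smooth* function of age, so every observation informs the norm at every
age, instead of cutting the sample into age brackets.

`bdrnorm` implements the Gaussian location-scale version of this idea as a
Bayesian distributional regression:

$$ y_i \mid x_i \sim N\!\big(\mu(x_i),\, \sigma(x_i)^2\big), \qquad
   \mu(x) = B(x)\beta_\mu, \qquad \log \sigma(x) = B(x)\beta_\sigma, $$

where $B(x)$ is a B-spline basis in age and each coefficient vector has a
Gaussian prior. The log link keeps $\sigma$ positive. Both distributional
parameters use the same knots, which is what makes prior transfer (below)
a one-to-one mapping between stage-one posterior and stage-two prior.

Percentiles, z-scores and IQ-type scores all derive from the fitted pair
$(\hat\mu(x), \hat\sigma(x))$: the percentile of score $y$ at age $x$ is
$\Phi\big((y-\hat\mu(x))/\hat\sigma(x)\big)$, and centile curves
$\hat\mu(x) + \hat\sigma(x)\Phi^{-1}(p)$ cannot cross in a location-scale
model — one of the main arguments for regression-based norming.

## P-splines

Each term is a penalized B-spline (P-spline): a rich equally spaced basis
plus a quadratic penalty $\beta^\top K \beta / \tau^2$ with
$K = D_r^\top D_r$, the $r$-th order difference penalty. The smoothing
variance $\tau^2$ plays the role of the inverse penalty weight and gets an
inverse-gamma prior, giving conjugate Gibbs updates.

Choices the underlying methodology leaves open, fixed here as package
defaults (all overridable through `make_knots()`):

* **Degree 3 (cubic).** The universal P-spline default.
* **Penalty order 2.** Second differences; the null space contains
  constant and linear coefficient sequences, so each term absorbs its own
  intercept and no separate intercept column is used.
* **24 equally spaced inner knots** over the observed age range is the
  convention used throughout the norming workflow here (and is what AICc
  selection typically supports for samples of this kind); the count is a
  parameter everywhere.
* **Boundary knots by equal-spacing extension**, not replication, so the
  difference penalty treats boundary coefficients exactly like interior
  ones. The basis is a partition of unity on the inner knot range, and
  evaluation outside that range is an error by design: callers clamp ages
  to the bounds first (`clamp_ages()`), which is also the documented
  treatment of testees slightly outside the normative age range.

## The three priors

* **Weakly informative**: $\beta \sim N(0, \tau^2 K^{-})$. Encodes only
  smoothness. This is the prior for a first (stage-one) fit.
* **Fixed effects**: $\beta \sim N(m, \hat P^{-1})$ where $m$ and
  $\hat P$ are the posterior mean and posterior precision of an earlier
  fit (old norms, another country's norms). No $\tau^2$ scaling and no
  additional penalty: the stage-one fit was itself penalized, so the
  transferred precision already encodes smoothness. MCMC works.
* **Posterior mode**: $\beta \sim N(m, \tau^2 \hat P^{-1})$, the
  transferred prior with a free scale. Because this construction combines
  the transferred precision with the second stage's penalty structure,
  sampling is not supported; fits use the posterior-mode optimiser
  instead. `fit_mcmc()` refuses this prior with an explanatory error, as
  does the CLI.

The posterior precision is extracted as the inverse of the sample
covariance of the pooled post-burn-in draws (the most direct reading of
"posterior precision matrix"; the curvature at the mode would be an
alternative). A relative ridge of $10^{-8}\,\mathrm{tr}(S)/p$ is added
before inversion so that nearly degenerate draw covariances still invert;
exactly degenerate ones are an error.

One smoothing variance is used **per term**, not per basis function: the
prior laws above use a single scalar $\tau^2$, and the single-$\tau$
P-spline prior is the standard construction. The inverse-gamma
hyperparameters default to the vague $a = b = 10^{-4}$.

## Estimation

`fit_mcmc()` runs Metropolis-within-Gibbs with iteratively weighted least
squares (IWLS) proposals, two sequentially run chains seeded `seed` and
`seed + 1`, 2000 iterations each with 500 burn-in by default:

* The $\mu$ block has a Gaussian full conditional (identity link), so it
  is a Gibbs draw — the IWLS proposal is exact there.
* The $\sigma$ block uses the Fisher-scoring weight 2 per observation and
  working response $z_i = \eta_i + (r_i^2 e^{-2\eta_i} - 1)/2$. The
  proposal precision does not depend on the current state, so only the
  proposal mean moves; the MH correction uses the reverse-mean proposal
  density. If mid-burn-in acceptance falls below 5% the proposal spread is
  halved once; a burn-in with zero acceptances is an error advising a
  smaller `step_scale`. In practice acceptance sits around 0.9.
* $\tau^2$ is drawn exactly from its inverse-gamma full conditional with
  shape $a + \mathrm{rank}(K)/2$ and rate
  $b + \beta^\top K \beta / 2$. For fixed-effects terms $\tau^2$ is inert
  (drawn from its prior) and does not touch the coefficients.

The linear predictor for $\log\sigma$ is bounded to $[-20, 20]$ inside
the fitting routines to prevent numeric collapse of the scale; the bound
is far outside any plausible fitted range.

`fit_posterior_mode()` maximizes the same log-posterior by alternating
exact penalized least-squares updates for $\beta_\mu$, step-halved Fisher
scoring for $\beta_\sigma$ (ascent is guaranteed by the halving), and
closed-form mode updates $\tau^2 = \mathrm{rate}/(\mathrm{shape}+1)$.
Convergence is declared when the log-posterior gain drops below `tol`
($10^{-6}$ by default); non-convergence is an error that prints the tail
of the objective trace.

Initialization is deterministic: $\beta_\mu$ from (barely ridged) least
squares, $\beta_\sigma$ from the log of a moving-window residual SD
projected on the basis, $\tau^2 = 10$. Every stochastic operation is a
pure function of its inputs and `seed`; equal seeds give bit-identical
draws.

Convergence is monitored with the Gelman-Rubin potential scale reduction
factor computed per spline coefficient over the retained, unpooled
chains; values below 1.1 are taken as converged. Identical chains give
$\sqrt{(n-1)/n}$, slightly below 1, which is the expected floor.

`select_knots_aicc()` picks the inner-knot count by the corrected AIC,
$-2\hat\ell + 2p + 2p(p+1)/(n-p-1)$. The effective parameter count $p$ is
the sum of the smoother-matrix traces of the two terms plus one per
smoothing variance, since a penalized term uses fewer degrees of freedom
than it has coefficients; this bookkeeping is a package choice (the
methodology does not pin it down). Ties break toward fewer knots.

## The synthetic world

The generator emulates an intelligence-test-like normative population on
ages 5–21: mean raw score rising steeply in childhood and flattening
toward adulthood, with a mildly U-shaped SD,

$$ \mu(a) = 100\,(1 - e^{-(a-4)/6}), \qquad
   \sigma(a) = 8 + 2\,\big((a-13)/8\big)^2 . $$

These formulas are documented stand-ins: the real fitted norming models
that motivated this package are estimated on licensed normative data and
are not public. Ages are noiseless equally spaced design points including
both endpoints (the simulation design of the methodology), not draws from
an age distribution. Scores are conditionally Gaussian — which is exactly
the model assumption, so a green recovery test establishes correctness of
the estimator under its own model, *not* robustness to skewness, floor
effects, or discreteness of real test scores.

Prior misspecification — the mismatch between the population behind the
prior and the population being normed — comes in five levels: none, a
constant shift in $\mu$, a multiplicative shift in $\sigma$, both, and an
age-dependent shift in $\mu$. Default magnitudes (also stand-ins, scaled
to the population's mean SD $\bar\sigma \approx 8.7$): $\Delta\mu = 0.3\,
\bar\sigma$, $\sigma$-inflation factor 1.2, and a linear ramp from 0 at
age 5 to $0.6\,\bar\sigma$ at age 21. All constants live in one config
block and are arguments of `misspecification_spec()`.

## The simulation study

`run_study()` crosses prior type (weakly informative / fixed effects /
posterior mode), misspecification level, stage-one size
$N_{prior} \in \{500, 1000, 2000\}$ and stage-two size
$N_{norm} \in \{250, 500, 1000\}$. Each replicate generates stage-one
data, fits it with the weakly informative prior, extracts the posterior
mean/precision, generates (possibly misspecified) stage-two data, fits it
with the condition's prior, and scores the result with the percentile
RMSE: estimated vs true percentiles on a $1000 \times 1000$ grid of
equally spaced ages and scores spanning true z-scores in $[-3, 3]$ (the
reporting range of norming practice), root-mean-squared on the
probability scale.

Seeding policy: stage-one fits depend only on $(N_{prior},$ replicate$)$
and are cached and shared across prior types and misspecification levels;
stage-two noise depends on the misspecification level, $N_{norm}$ and the
replicate but *not* on the prior type, so prior types are compared on
identical data within a replicate (a paired design). The weakly
informative path never touches $N_{prior}$, making its independence of
$N_{prior}$ structural rather than statistical.

The acceptance suite runs a reduced-scale version — 25 replicates, 1000
iterations with 250 burn-in, a subset of the factor grid — chosen for
runtime and fixed before its results were inspected. It checks the
qualitative findings (informative fixed-effects priors help under
age-independent misspecification, hurt increasingly with $N_{prior}$ under
age-dependent misspecification, RMSE decreases in $N_{norm}$, the
posterior-mode prior never dominates), not numeric values: the original
study's numbers depend on unpublished population models and on
$R = 1000$ replicates.

## Numerical choices and degenerate inputs

* Knot serialization uses 17 significant digits throughout (JSON and CSV),
  so stage-two fits reuse stage-one knots bit-exactly and
  serialize/reload/predict round trips are bit-identical.
* Rank and PSD checks on precision cores use a relative eigenvalue
  tolerance of $10^{-8}$.
* Normal-equation matrices carry a relative jitter of $10^{-10}$ on the
  diagonal so that small-sample fits with rank-deficient designs stay
  solvable.
* Centile levels must lie strictly inside $(0,1)$; boundary probabilities
  are rejected rather than mapped to $\pm\infty$.
* `credible_band()` needs posterior draws; mode fits are rejected. With
  fewer retained draws than requested it resamples with replacement
  (seeded); with more, it subsamples without replacement (seeded). Curves
  reported elsewhere are plug-in curves at the posterior mean of the
  coefficients; draw-wise curves are used only inside the band
  computation. (Whether published centile plots use plug-in or draw-wise
  means is not knowable from the method description; plug-in is the
  package's choice and the band's `mean` column shows the draw-wise
  alternative.)

## A note on the posterior-mode prior

The $N(m, \tau^2 \hat P^{-1})$ prior combined with joint maximization over
$(\beta, \tau^2)$ and a vague inverse-gamma hyperprior is degenerate: the
profile log-posterior grows like $-(a + p/2 + 1)\log\tau^2 - b/\tau^2$ as
$\beta \to m$, so the global mode sits at
$\tau^2 \approx b/(a + p/2 + 1) \sim 10^{-5}$, which pins the stage-two
coefficients at the transferred prior mean. The optimiser finds this basin
within a few iterations. Practically, a fit with this prior reproduces the
stage-one model almost exactly and learns nearly nothing from the new
sample — consistent with (and a plausible mechanism for) its consistently
inferior performance relative to the other two priors. The fixed-effects
prior, which drops the $\tau^2$ scale, has no such degeneracy and is the
recommended transfer prior.

## Known limitations

* Gaussian conditional distributions only. Skewed or bounded scores
  (floor/ceiling effects) need other response families, which this
  package deliberately does not implement.
* One predictor (age); no sex/education covariates, no multi-term
  predictors per parameter.
* Integer test scores are treated as continuous, as is standard in this
  literature.
* No monotonicity constraint on $\mu(a)$; a fitted mean can dip where the
  data do.
* The recovery accuracy of $\sigma(a)$ at realistic sample sizes is
  bounded by sampling noise: at $n = 5000$ with 24 knots the posterior
  relative SD of $\sigma(a)$ is about 2.3%, so pointwise errors of 2–6%
  are expected even for a perfectly calibrated fit (an independent REML
  location-scale GAM shows the same error level on identical data).
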