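---
title: "Methods: the LN-CASS prior, its model variants and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the LN-CASS prior, its model variants and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncass)
```

## The prior

The discrete spike-and-slab prior writes a regression coefficient as
$\beta = \gamma \,\tilde\beta$ with a Bernoulli inclusion indicator
$\gamma \in \{0, 1\}$ and a diffuse slab $\tilde\beta \sim N(0, \tau^2)$. It
is the reference point for Bayesian variable selection, but its discrete
component forces samplers to explore $2^p$ support configurations.

The logit-normal continuous analogue of the spike-and-slab (LN-CASS)
replaces the Bernoulli indicator with a continuous weight
$\lambda \in (0,1)$ that follows a logit-normal distribution,

$$\lambda = \mathrm{sigm}(\eta), \qquad \eta \sim N(\mu_\lambda,
\sigma_\lambda^2), \qquad \beta = \tau\,\lambda\,z, \qquad z \sim N(0,1).$$

With $\sigma_\lambda$ large the logit-normal is U-shaped, piling its mass
near 0 and 1, so $\beta$ behaves like a spike-and-slab draw while the joint
posterior stays continuous and differentiable — amenable to gradient-based
MCMC. $\lambda$ is directly interpretable as an approximate inclusion
probability. The logit-normal is preferred over a Beta with the same shape
because it is a deterministic transform of a normal variable: the whole
model can be written in terms of (conditionally) standard normal latents,
which is also how this package parameterises it internally
($\eta = \mu_\lambda + \sigma_\lambda u$, $u \sim N(0,1)$; the non-centred
parameterisation).

### Hyperparameters

* `tau` (default **5**) — the slab standard deviation. For standardised
  predictors this is a vague prior on non-zero coefficients.
* `sigma_lambda` (default **10**) — controls the quality of the
  spike-and-slab approximation; larger is closer to the discrete mixture.
  Results are insensitive to increases beyond the default.
* `mu_lambda` / `a` — the prior inclusion probability enters through
  $\mu_\lambda = \mathrm{logit}(a)$, because $\mathrm{sigm}(\mu_\lambda)$
  is the median of the logit-normal. The package accepts either one;
  the default is $a = 1/2$ ($\mu_\lambda = 0$), reflecting prior
  indifference, since no canonical default exists.

## Model variants

All variants place a vague $N(0, 10^2)$ prior on the intercept. The
gaussian noise standard deviation gets a half-normal(0, 5) prior and is
sampled on the log scale. Both choices are the package's own (weakly
informative but proper); posterior results at the study scales are
insensitive to them.

**Flat** (`build_flat_model`): independent LN-CASS priors
$\beta_j = \tau \lambda_j z_j$ per coefficient, gaussian (identity link) or
binomial (logit link) likelihood.

**Grouped** (`build_grouped_model`): a complexity ladder over pre-specified
predictor groups — exclude the group, include it with one shared
coefficient, or let members deviate:

$$\beta_{gj} = \tau\,\lambda_g\,(z_g + \lambda_{gj} w_{gj}).$$

$\lambda_g \to 0$ removes the whole group exactly; $\lambda_{gj} \to 0$
collapses member $j$ onto the shared effect $\tau \lambda_g z_g$. Each rung
of the ladder multiplies a fresh logit-normal weight onto the previous one.
The algebraic placement of the deviation term was a genuinely open design
point; this form was chosen because both rungs are exact limits, and
because with singleton groups and the member rung switched off it reduces
*identically* (same log-density) to the flat model — a nesting property the
test suite pins down.

**Hierarchical GAM** (`build_hierarchical_gam`, binomial only): each
covariate effect is a piecewise-linear function
$f_i(x) = c_{i0}\,x + \sum_k c_{ik} \max(0, x - \kappa_k)$ built from an
identity column and hinge functions at knots $\kappa_k$ (default: 5 knots
equally spaced at $k/6$ on $[0,1]$; covariates are expected on the unit
interval, which `scale_unit_interval()` produces). Hinges are the minimal
basis that nests linearity exactly. The ladder here is
no effect → linear effect → nonlinear effect:

$$c_{i0} = \tau\,\lambda_i\,z_i, \qquad
  c_{ik} = \tau\,\lambda_i\,\lambda_i^{\mathrm{nl}}\,w_{ik},$$

so $\lambda_i \to 0$ removes the covariate and
$\lambda_i^{\mathrm{nl}} \to 0$ leaves a pure linear term. With zero knots
the GAM is identical to flat logistic regression, another tested nesting.

## Inference

The package samples each model's joint posterior with its own adaptive
Hamiltonian Monte Carlo sampler operating on the analytic gradients each
model spec carries (the gradients themselves are validated against central
finite differences in the test suite). Warmup runs in two phases: step-size
adaptation by dual averaging (target acceptance 0.9) under a unit metric,
then diagonal mass-matrix estimation from the second half of phase one and
re-adaptation of the step size under the new metric. Trajectory lengths are
jittered uniformly around a nominal physical length of 1.6 (capped at 128
leapfrog steps) to avoid resonances. Non-finite Hamiltonians are rejected
and counted as divergences; chains that fail to initialise are re-seeded up
to three times. Defaults are 4 chains of 1000 warmup + 1000 retained
draws. Gradient-based sampling is what makes the continuous relaxation pay
off: the U-shaped posterior over each $\lambda$ is traversed without any
discrete moves.

Convergence is monitored with the split Gelman–Rubin statistic
(`gelman_rubin`): each chain is halved before computing the
between-/within-variance ratio, which is strictly more conservative than
the classic statistic and also flags intra-chain drift. The fitting driver
warns prominently when any split R-hat exceeds 1.1.

Summaries (`summarize_posterior`) apply the coefficient map per draw and
then summarise — medians, means and central 90% intervals of the mapped
coefficients — rather than mapping summary statistics of the latents,
which would be wrong for these nonlinear maps. Per-predictor inclusion is
reported as the posterior mean of the *top-layer* $\lambda$ only (group
level for grouped models, covariate level for the GAM); lower layers are
reported separately and never silently multiplied together, since each
$\lambda$ approximates an inclusion probability at its own level of the
hierarchy. Hard selection, when needed, uses `select_top_k`: keep the $k$
coefficients largest in absolute posterior median, ties broken by lower
index for reproducibility.

## Evaluation metrics

`roc_auc` computes the ROC curve over distinct thresholds and its
trapezoidal area; ties count one half (Mann–Whitney convention), which
makes the area exactly the concordance probability — the probability a
random positive outscores a random negative. An independent rank-based
route (`auc_concordance`) is kept in the module and the two are required
to agree to $10^{-12}$. Sparsity recovery is scored by
`sparsity_recovery_auc`: the AUC of $|\hat\beta|$ against the truth's
support, i.e. the probability that a truly non-zero parameter is estimated
larger in magnitude than a truly zero one. Parameter accuracy is the mean
absolute error over the coefficient vector (intercept excluded).

`run_cv` drives repeated stratified k-fold CV and leave-one-out CV. Whether
folds should be stratified is this module's documented choice (it keeps
folds fittable under class imbalance). Class-balanced LOOCV drops one
randomly chosen opposite-class observation from each training fold
(seeded per fold, since no particular scheme is canonical), making class
proportions identical across folds and removing a bias in pooled LOOCV AUC
estimates.

## Preprocessing

Deterministic column transforms (`log1p_columns`, `scale_unit_interval`,
`standardize_columns`) fit their constants once and return a serialisable
record so the same constants can be re-applied to held-out data — the
leakage-safe pattern for use inside CV. The standard deviation uses the
$n-1$ denominator. Re-applied unit-interval scaling clamps out-of-range
values into $[0,1]$ and counts the clamps. Missing values are rejected
outright; imputation is deliberately out of scope and must happen upstream.

`wald_screen` ranks predictors for $p \gg n$ classification problems by the
absolute Wald $Z$ of univariate logistic fits. The fits carry a tiny ridge
penalty ($10^{-4}$), because expression-style matrices routinely contain
perfectly separating columns whose unpenalised $Z$ is undefined; the guard
gives them a large finite score instead of a crash. Whether screening runs
once or per CV fold is exposed to the caller; per-fold is the leakage-safe
default recommendation.

## The synthetic study

`default_scenarios()` defines three grouped linear-regression settings at
$n = 100$ with $p = 20, 70, 120$. Designs are unit Latin hypercubes (every
column stratified into $n$ equal bins with one point per bin), noise is
i.i.d. zero-mean Gaussian with `noise_sd = 1` (a neutral choice: signal
coefficients of magnitude 1–3 against unit noise give a realistic
signal-to-noise for $n = 100$). Each scenario contains several all-zero
groups, one group sharing a single non-zero coefficient, and one
heterogeneous group with similar but unequal values — the three behaviours
the grouped prior is built to distinguish. The exact coefficient tables are
package fixtures collected in one editable place (`R/scenarios.R`).

`generate_gam_scene()` emulates a nonparametric-classification setting: ten
uniform covariates of which one acts through a centred quadratic
($12(x-\tfrac12)^2 - 1$), one through a centred linear term ($4(x-\tfrac12)$),
and eight are pure noise. The amplitudes are chosen so class probabilities
span roughly 0.05–0.95: strong enough that the ladder's behaviour
(inclusion for both signals, nonlinearity gate only for the quadratic) is
identifiable at $n = 150$, which is the scene's purpose as a known-truth
fixture.

What the generators deliberately do **not** emulate: correlated designs,
heavy-tailed or heteroscedastic noise, missingness, and measurement error.
Passing tests on these fixtures therefore demonstrate correctness of the
implementation and qualitative behaviour of the prior, not performance
guarantees on real biological data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the $p = 20$ scenario with
4 chains × (1000 + 1000) iterations and the GAM scene at $n = 150$ with
4 × (800 + 800); these desk-scale sizes give stable split R-hats below 1.1
while keeping a full run in minutes. The $p = 70$ and $p = 120$ scenarios
use the same code path and are intended for longer scheduled runs.
Inclusion weights are clamped to $[10^{-12}, 1-10^{-12}]$ before any
logit/log to avoid overflow at $\sigma_\lambda$ in the 10–50 range
(double-precision `sigm` saturates to exactly 0/1 beyond $|\eta| \approx 37$).
Tie-breaks (top-$k$ selection, Wald screening) always resolve to the lower
index so results are stable across runs. Degenerate inputs — constant
columns at scaling time, zero-variance columns at standardisation, single
groups with no members, single-class AUC — are rejected with informative
errors rather than silently handled.

## Known limitations

* The sampler is plain adaptive HMC with a diagonal metric; strongly
  correlated or very high-dimensional posteriors ($p$ in the thousands)
  would benefit from a dynamic-trajectory sampler and will be slow here.
* The coefficient/inclusion posterior is multimodal by construction
  (λ near 0 with large z vs λ near 1 with small z describe similar β);
  multiple chains plus split R-hat are the guard, and the fitting driver
  surfaces R-hat violations rather than hiding them.
* No imputation, no interaction terms, no non-logit links, and no
  variational approximation; these are out of scope.
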