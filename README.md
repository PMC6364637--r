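# lncass

Bayesian sparse regression with the **logit-normal continuous analogue of
the spike-and-slab (LN-CASS) prior** — simultaneous shrinkage, variable
selection and parameter estimation for the p ≫ n problems typical of
biological and medical data (expression matrices, metabolite panels,
grouped immunological counts), for applied statisticians who want
interpretable classical models rather than black-box learners.

## The prior

The discrete spike-and-slab writes a coefficient as β = γ·β̃ with a
Bernoulli inclusion indicator γ and slab β̃ ~ N(0, τ²); it is the gold
standard of Bayesian variable selection but combinatorially intractable.
LN-CASS relaxes the indicator into a continuous weight with a U-shaped
logit-normal distribution:

    λ = sigm(η),   η ~ N(μ_λ, σ_λ²),   β = τ · λ · z,   z ~ N(0, 1)

With σ_λ large, λ piles up near 0 and 1, so β behaves like a
spike-and-slab draw while the posterior stays continuous and
differentiable — which is what lets gradient-based MCMC sample it. λ is
read as an approximate inclusion probability; setting μ_λ = logit(a)
encodes a prior inclusion probability a (defaults: τ = 5, σ_λ = 10,
a = 0.5).

Because each λ is one rung of a multiplicative ladder, the prior extends
to hierarchical complexity structures:

* **grouped** — no effect → shared group effect → individual member
  effects: β_gj = τ · λ_g · (z_g + λ_gj · w_gj);
* **hierarchical GAM** (logit link, hinge basis) — no effect → linear
  effect → nonlinear effect: linear coefficient τ·λ_i·z_i, knot
  coefficients τ·λ_i·λ_i^nl·w_ik.

Inference is adaptive Hamiltonian Monte Carlo over analytic-gradient
log-densities, with split Gelman–Rubin diagnostics, posterior summaries,
ROC/AUC + MAE metrics, class-balanced LOOCV, deterministic preprocessing
transforms (log1p, unit-interval and z-score scaling, ridge-guarded Wald
screening) and a seeded simulation-study harness. See
`vignettes/lncass-methods.Rmd` for the full model and design account.

## Worked example

Generate the default grouped simulation scenario (n = 100 observations,
p = 20 predictors in 4 groups: one heterogeneous, one shared-coefficient,
two all-zero), fit the grouped LN-CASS model, and score recovery:

```r
library(lncass)

scen    <- default_scenarios()[[1]]
gen     <- generate_grouped_regression(scen)
model   <- build_grouped_model(gen$data, gen$groups)
samples <- run_mcmc(model, chains = 4, warmup = 1000, draws = 1000, seed = 1)
summ    <- summarize_posterior(samples)

sparsity_recovery_auc(summ$coefficients$median, gen$truth$beta_true)
#> [1] 1
mae(summ$coefficients$median, gen$truth$beta_true)
#> [1] 0.1168277
mae(ols_fit(gen$data)$beta, gen$truth$beta_true)   # least-squares baseline
#> [1] 0.3267979
summ$max_rhat
#> [1] 1.093984
```

A recovery AUC of 1 means every truly non-zero coefficient is estimated
larger in magnitude than every truly zero one; the posterior-median MAE is
about a third of the OLS error because the zero groups are shrunk to
essentially 0 and the shared group is pooled; all split R-hats are below
the conventional 1.1 bar. The per-predictor approximate inclusion
probabilities sit in `summ$inclusion` (≈ 0.7–0.8 for signal groups, below
0.1 for the zero groups on this run).

## Command line

```sh
Rscript inst/cli/lncass.R fit      --config run.txt        # preprocess→fit→summaries
Rscript inst/cli/lncass.R evaluate --config run.txt        # cross-validated AUC
Rscript inst/cli/lncass.R simulate --scenario 1 --out dir  # write synthetic dataset
Rscript inst/cli/lncass.R study    --out dir               # simulation study table
Rscript inst/cli/lncass.R screen   --input data.csv --k 50 # Wald screen
```

Run configuration is flat sectioned `key = value` text; every run writes
its fully resolved config, draws, summaries and an R-hat report beside its
outputs.
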