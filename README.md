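# retrosse

State-dependent diversification analysis of LINE-1 (L1) retrotransposition
activity in human genomes.

## What this package is for

Full-length L1 elements are the only autonomously active retrotransposons
in humans. Given a phylogeny of genomic L1 insertions whose tips carry
cell-culture retrotransposition activities (percent of the reference
element L1_RP, binarized at 25%), `retrosse` estimates how activity shapes
L1 population dynamics:

* **BiSSE likelihood** — a binary-state speciation–extinction model with
  rates λ₀, λ₁ (new-insertion rates of low/high-activity lineages), μ₀, μ₁
  (loss rates) and q₀₁, q₁₀ (activity transitions), all per
  substitution/site, computed by post-order pruning of the standard BiSSE
  ODEs in compiled code, pooled over a sample of trees by log-sum-exp.
* **Change-point extension** — both speciation rates rescaled by a shared
  factor in epochs older than boundaries given in generations (converted
  with a substitution rate, default 2.5×10⁻⁸ per nucleotide and
  generation), one extra parameter per boundary.
* **Constrained ML fitting and AIC comparison** — nine built-in constraint
  models, multi-start optimisation on log-rates, exact AIC bookkeeping.
* **Asymptotic growth** — the 2×2 dynamics matrix
  `[[λ₀−μ₀−q₀₁, q₁₀], [q₀₁, λ₁−μ₁−q₁₀]]`, its dominant eigenvalue (L1
  insertions per nucleotide substitution), the stationary low/high mix from
  the eigenvector, per-generation rates and doubling times.
* **Mk2 + reversible-jump MCMC** — a Bayesian analysis of the transition
  rates alone (no state-dependent branching), jumping across four rate
  constraints and resampling trees from the sample each iteration.
* **Forward simulator** — Gillespie simulation of trees and tip activities
  under known parameters, so every inference stage is validated end-to-end
  without external data.

## Worked example

Simulate a 150-tip dataset at a high-asymmetry regime, fit the
zero-extinction model, and read off the implied L1 dynamics:

```r
library(retrosse)

truth <- bisse_params(lambda0 = 10, lambda1 = 412, mu0 = 0, mu1 = 0,
                      q01 = 31, q10 = 360)
sim <- simulate_bisse(sim_config(truth, n_tips = 150), seed = 3)
mean(sim$states$state)          # fraction of high-activity tips
#> [1] 0.32

fit <- fit_model(tree_sample(list(sim$tree)), sim$states,
                 builtin_constraints()[["mu0=mu1=0"]],
                 n_starts = 4, seed = 1)
fit
#> BiSSE fit [ mu0=mu1=0 ]  df = 4
#>   logLik = 598.21192   AIC = -1188.4238
#>   rates: lambda0=  5.116, lambda1=420.918, mu0=  0.000, mu1=  0.000,
#>          q01= 30.824, q10=345.870

asymptotic_growth(dynamics_matrix(fit))
#> Asymptotic L1 dynamics
#>   growth rate: 140 insertions per nucleotide substitution
#>   per generation: 3.5e-06
#>   doubling time: 2e+05 generations
#>   equilibrium mix: 67.7 % low / 32.3 % high activity
```

The fit recovers the simulation truth (λ₁ ≈ 421 vs 412, q₁₀ ≈ 346 vs 360,
with the correct ordering λ₁ > q₁₀ > q₀₁ > λ₀), and the growth analysis
turns those rates into an interpretable statement: under the fitted rates
the L1 count grows by ~140 insertions per nucleotide substitution — about
3.5×10⁻⁶ per generation at 2.5×10⁻⁸ substitutions/generation, a doubling
time of ~2×10⁵ generations — with ~32% of elements high-activity at
equilibrium. (At the generating rates themselves the same analysis gives
127 insertions per substitution, 3.2×10⁻⁶ per generation and a 2.2×10⁵
generation doubling time; this replicate's estimates sit a little above.)

See `vignettes/l1-diversification-methods.Rmd` for the models, numerical
choices and the simulator's scope.

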