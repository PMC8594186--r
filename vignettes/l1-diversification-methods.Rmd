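---
title: "Models and methods for L1 retrotransposition dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for L1 retrotransposition dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrosse)
```

## The scientific problem

LINE-1 (L1) elements are the only autonomously active retrotransposons in
the human genome. Each full-length genomic L1 insertion can be assayed in
cell culture for its retrotransposition activity, expressed as a percentage
of the highly active reference element L1\_RP. A phylogeny of L1 insertions,
with tips labelled by their activity, carries information about three
processes at once: the rate at which active elements spawn new detectable
insertions, the rate at which insertions are lost, and the evolution of the
activity itself along lineages. `retrosse` implements the model stack needed
to separate these processes and to translate the fitted rates into
population-level L1 growth predictions.

## The BiSSE model and its likelihood

The core model is binary-state speciation and extinction (BiSSE): a
birth–death process on the tree whose per-lineage rates depend on a binary
character (high vs low activity, binarized at 25% of L1\_RP, ties counted as
high). The six rates — $\lambda_0, \lambda_1$ (new-insertion rates for low
and high activity), $\mu_0, \mu_1$ (loss rates) and $q_{01}, q_{10}$
(activity transitions) — are all measured per substitution per site, the
unit of the tree's branch lengths.

The likelihood is computed by post-order pruning. Along each branch the
extinction probabilities $E_i$ and partial likelihoods $D_i$ follow

$$
\frac{dE_i}{dt} = \mu_i - (\lambda_i + \mu_i + q_{ij}) E_i
  + q_{ij} E_j + \lambda_i E_i^2, \qquad
\frac{dD_i}{dt} = -(\lambda_i + \mu_i + q_{ij}) D_i
  + q_{ij} D_j + 2 \lambda_i E_i D_i,
$$

with $E_i(0) = 0$ and tip initialisation $D = 1$ for the observed state
(both states for unknown tips). At each internal node
$D_i = \lambda_i D_i^{\text{left}} D_i^{\text{right}}$.

Numerical choices that matter at the L1 scale, where fitted rates reach
hundreds per unit branch length on short trees:

* The per-branch ODEs are integrated in compiled code with an adaptive
  embedded Cash–Karp Runge–Kutta scheme, relative tolerance `1e-10` and
  absolute tolerance `1e-14` by default. These are deliberately tight — the
  integrator is cheap at this system size and the tight default keeps the
  likelihood accurate to ~`1e-8` relative even on monomorphic Yule data,
  where the closed form is known exactly.
* Partial likelihoods are renormalised at every node join with a log-scale
  accumulator, so no underflow occurs even on 150-tip trees at the fitted
  rates.
* $E$ is clamped to $[0, 1]$ against round-off; $D$ values in
  $[-10^{-12}, 0)$ are clamped to zero, anything more negative is a hard
  error naming the offending node.
* At a node the two children's $E$ vectors (equal in exact arithmetic) are
  averaged, which keeps the computed likelihood exactly invariant under
  swapping children.

### Root treatment

The root combination is not dictated by the model. The default weights each
root state by its relative partial likelihood (`weighted`), the convention
of the standard diversification tooling this package parallels; `flat`,
`equilibrium` (stationary frequencies of the transition process) and
`fixed` are available, and conditioning on survival of both root lineages
is a separate flag, off by default. Every fit records the options used, so
results are comparable only within one convention.

### Trees, units, and ultrametricity

BiSSE assumes all tips are sampled at the present, so trees must be
ultrametric; posterior tree samples are ultrametric only up to numerical
slack, and `check_ultrametric()` accepts a relative tolerance (default
`1e-3` of tree depth). Non-ultrametric trees are rejected for BiSSE but
perfectly valid for the Mk2 analysis, which places no constraint on branch
lengths. Epoch boundaries are specified in generations and converted to
branch-length units with a per-generation substitution rate
(default $2.5\times 10^{-8}$ per nucleotide per generation).

## Change-point extension

Human demography (a bottleneck ending roughly 4720 generations ago, an
expansion starting roughly 140 generations ago) plausibly modulates the
rate at which new insertions reach detectable population frequency. The
change-point model multiplies *both* speciation rates by a shared factor in
epochs older than each boundary; the most recent epoch always has factor 1,
and $\mu$, $q$ are unchanged. Branches spanning a boundary are integrated
segment-wise with $E$ and $D$ continuous across it. Each boundary adds
exactly one parameter; a boundary older than every tree root cannot move
the likelihood and is flagged as unidentifiable.

## Pooling over a tree sample

To propagate phylogenetic uncertainty, the per-tree likelihoods are summed
over the tree sample — `pooled_loglik()` returns
$\log \sum_i L_i$ via log-sum-exp. Summing rather than averaging adds the
same $\log N$ to every model's log-likelihood, so AIC *differences*, which
drive all model choices here, are unaffected.

## Constrained maximum likelihood and model comparison

Nine constraint models are built in (`builtin_constraints()`): the
unconstrained model, single ties ($\mu_0 = \mu_1$, $\lambda_0 = \lambda_1$,
$q_{01} = q_{10}$), single zero-fixes ($\lambda_0 = 0$, $q_{01} = 0$), zero
extinction ($\mu_0 = \mu_1 = 0$) and the two three-parameter combinations.
Optimisation is over log-transformed free rates, which makes the
non-negativity constraint implicit and conditions the problem much better
than a linear-scale constrained optimiser; the optimum is the same. The
default strategy is Nelder–Mead with a polishing restart, from one
moment-based start ($\hat\lambda \approx (n-1)/T$) plus nine seeded
log-uniform draws on $[10^{-2}, 10^4]$; non-finite likelihoods during the
search are penalised rather than fatal. `extra_starts` lets a caller chain
the optimum of a nested model into a more general fit, which guarantees the
likelihood-nesting inequality in comparisons. AIC is computed as
$2\,\mathrm{df} - 2\log L$ at full precision; ranking ties are broken by
fewer parameters, then by constraint id.

## Asymptotic growth

The fitted rates define a linear system for the expected numbers of low-
and high-activity insertions:

$$
\frac{d\mathbf{x}}{dt} =
\begin{bmatrix}
\lambda_0 - \mu_0 - q_{01} & q_{10} \\
q_{01} & \lambda_1 - \mu_1 - q_{10}
\end{bmatrix} \mathbf{x}.
$$

The dominant eigenvalue is the asymptotic growth rate of the L1 count per
nucleotide substitution and the associated eigenvector the stationary
low/high mix. Because the matrix is 2×2 with non-negative off-diagonals,
the spectrum is real and the package solves the quadratic in closed form
rather than calling a generic eigensolver — exact, and directly testable.
The eigenvector sign is fixed by non-negativity and normalised to sum 1.
Per-generation rates and doubling times ($\ln 2 / r$) follow from the unit
conversion; non-positive growth reports an infinite doubling time.
`forward_integrate()` solves the same ODE in log-total/composition form (no
overflow at large times) and serves as an independent numerical check of
the eigenanalysis.

A note on reporting: with the best-fit rates rounded to the integers shown
in the fitted-model table, the stationary high-activity fraction computed
from the eigenvector is ≈29%, while an equilibrium proportion of 25% is
sometimes quoted alongside these rates from unrounded internal estimates.
The package reports what its inputs imply and does not adjust toward any
external figure.

## Mk2 and the reversible-jump sampler

The Bayesian track models only the activity transitions: a two-state
continuous-time Markov chain on the tree (Mk2), with the closed-form
transition probabilities and Felsenstein pruning. The root defaults to the
stationary frequencies, under which the likelihood is invariant to
re-rooting along a branch. This track deliberately ignores
state-dependent branching — the two tracks answering the same asymmetry
question with different assumptions is the point.

`run_mcmc()` samples $(q_{01}, q_{10})$ with log-scale random-walk
Metropolis moves, resamples a tree uniformly from the sample each iteration
(accepted by likelihood ratio), and, with `rj = TRUE`, jumps among four
constraints: both rates free, equal rates, $q_{01} = 0$, $q_{10} = 0$,
with a uniform model prior. Design choices, all declared rather than
inferred from any external tooling:

* **Priors**: independent exponentials with mean 100 per free rate — a
  weakly informative scale for transition rates of order tens to hundreds
  per substitution/site; configurable.
* **Between-model moves** propose every free rate of the destination model
  from its prior, so the acceptance ratio reduces to the likelihood ratio.
  This is simpler than split/merge proposals centred on the current rates
  and mixes somewhat more slowly across models, but it is exactly valid,
  easy to audit, and — with the likelihood switched off — lets a test
  verify that the sampler reproduces its priors (model probabilities 1/4
  each; marginal rate mean = prior mean × 3/4, since each rate is
  structurally zero in one of the four models).
* **Adaptation**: the proposal scale is tuned toward ~30% acceptance during
  the first quarter of the chain and then frozen; the whole trace is
  reproducible from the seed. Defaults: burn-in fraction 0.25 (applied in
  `posterior_summary()`), thinning 10.

## The synthetic-data generator

No deposited tree sample accompanies the real analysis, so all validation
runs on simulated data. `simulate_bisse()` is a Gillespie simulation of the
state-dependent birth–death-transition process: each lineage in state $i$
waits an exponential time with total rate
$\lambda_i m(t) + \mu_i + q_{ij}$ and the event type is chosen
proportionally; change-point multipliers $m(t)$ are handled by never
stepping across an epoch boundary. Two stop rules:

* `n_tips`: the run stops when a birth would raise the extant count past
  the target, and the present is the time of that (unapplied) birth. This
  avoids both the zero-length tip branches of stopping exactly at the
  $n$-th birth and the bias of naive stopping.
* `max_time`: fixed time span, needed whenever a change-point truth is
  simulated (its boundaries are times before the present, which must be
  known in advance).

Extinct lineages are pruned to give the reconstructed tree, ultrametric by
construction. Runs in which the clade dies out are retried up to a cap,
then reported as an error.

Raw activities are generated conditionally on the latent state
(`activity_model()`): scaled-Beta below the 25% threshold for low-activity
tips, a shifted exponential above it for high-activity tips. These
distributions are this package's own choice — no generative description of
activity values exists to copy — and they respect the threshold by
construction, so binarization recovers the latent states exactly.
`make_fixture_bundle()` writes a multi-tree newick file (the reconstructed
tree with multiplicative log-normal branch jitter, re-ultrametrized via the
terminal branches, default $\sigma = 0.05$), an activity table and a truth
JSON. The jitter is a cheap stand-in for posterior branch-length spread and
is labelled synthetic; it is **not** a posterior sample — it has no
topological variation and no model-based correlation structure.

What passing simulation-based tests does and does not show: recovery at the
fitted regime demonstrates that the estimator is consistent and the
pipeline unbiased *under the model*; it cannot validate the model against
real L1 data, where detection bias toward high-frequency insertions,
coalescent-vs-retrotransposition time-scale mixing and non-ultrametric
posterior slack all intrude.

## Problem sizes used in the tests

The validation suite runs at deliberately moderate sizes chosen to exercise
every code path at the fitted parameter scale: oracle comparisons on 10–20
tip trees (50 random instances against an independently coded fixed-step
RK4 pruning), parameter recovery on 20 datasets of 150 tips each at the
best-fit rates with the zero-extinction constraint, reversible-jump model
choice on 8 replicates of 80 tips, and a 40 000-iteration prior-sampling
check. These sizes give stable pass/fail behaviour at fixed seeds while
keeping the full suite in the minutes range.

One calibration fact worth stating plainly: at the fitted regime the truth
puts $\lambda_1$ and $q_{10}$ only 14% apart (412 vs 360), and on a single
150-tip tree the ML estimates of that pair flip order in roughly a quarter
of replicates (the recovery test measures 70% full rank-order recovery on
its 20 fixed seeds, 75% over 40). The estimates themselves are essentially
unbiased — replicate means land on the truth — so this is sampling noise
inherent to the dataset size, not an estimator defect; recovering the full
four-rate ordering reliably needs either a larger margin between the rates
or more data than one tree of this size carries.

## Known limitations

* Only two states (no multi-state or hidden-state extensions) and no
  sampling-fraction correction.
* The change-point factor is shared by both speciation rates by design;
  state-specific epoch effects are not expressible.
* The likelihood treats every internal node as a retrotransposition event;
  on real data internal nodes are coalescent events whose time scale can
  blur into the insertion process.
* The fixture jitter emulates branch-length spread only; tests that pool
  over such a sample exercise the pooling machinery, not genuine
  phylogenetic uncertainty.
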