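---
title: "Two-way minimization: model, design choices and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-way minimization: model, design choices and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twowaymin)
```

## The allocation problem

In a two-arm trial with very few subjects, simple randomization routinely
leaves the arms unequal in size and unequal in the distribution of
prognostic factors, which costs power and invites chance confounding.
Classical minimization (Pocock–Simon) repairs the covariate balance by
design, but its near-deterministic assignments are predictable, exposing
the trial to selection bias.

Two-way minimization tracks **two** imbalances between the treatment arm
(T) and the control arm (C):

* the arm-size imbalance $D_1 = |N_T - N_C|$, and
* a distributional imbalance $D_2 = \sum_k w_k D_k$, where $D_k$ is a
  distance between the two arms' level-proportion vectors of prognostic
  factor $k$ (weights $w_k \ge 0$, default 1).

For every new subject a Bernoulli draw with probability
$\pi(D_1) = 1 - (1-q)^{D_1}$ picks one of two comparison-based rules:

* **A1** (probability $\pi$): allocate to the arm with fewer subjects
  (fair coin if equal);
* **A2** (probability $1-\pi$): allocate to the arm whose *prospective*
  $D_2$ — the overall imbalance recomputed as if the subject joined that
  arm — is smaller (fair coin on ties).

Since $\pi(0) = 0$, a size-balanced trial decides purely on covariates;
as $D_1$ grows, the scheme increasingly insists on repairing the arm
sizes. Because the two rules only *compare* imbalances and the rule choice
is stochastic, every allocation decision is invariant to strictly
increasing transformations of $D_1$ or $D_2$ — the exact functional forms
carry no weight, only the orderings they induce. The test suite asserts
this by replaying allocation sequences under an exponentiated distance.

## Design choices in the imbalance machinery

Several ingredients of the published scheme are only pinned down up to
such monotone transformations, and we had to fix concrete forms:

* **Per-factor distance $D_k$.** We use the L1 distance
  $\sum_l |p_{T,kl} - p_{C,kl}|$: it is a standard distribution distance,
  reduces to $2|p_T - p_C|$ for a binary factor, and is bounded by 2. The
  distance is pluggable (`distance = "max"`, or any
  `function(pT, pC)`), and by the invariance above any strictly monotone
  alternative allocates identically.
* **Accrual function.** $\pi(D_1) = 1 - (1-q)^{D_1}$ is the canonical
  geometric form that is 0 at $D_1 = 0$, strictly increasing, and tends
  to 1. The tuning parameter defaults to $q = 0.05$, the compromise value
  identified by the evaluation study below. We accept the boundary values
  too: $q = 0$ is the pure covariate rule A2 (used by `q_sweep()` as the
  left end of the grid) and $q = 1$ forces rule A1 whenever the arms
  differ (useful for testing the size-rule in isolation).
* **Burn-in.** Level proportions are undefined while an arm is empty, so
  the trial starts with simple randomization until each arm holds at
  least `burn_in` subjects (default 1, the weakest sufficient condition);
  imbalance queries during burn-in raise a typed error rather than guess.
* **Ties.** Prospective imbalances are rationals with denominators
  $\le n$; differences below $10^{-12}$ are therefore genuine ties (not
  rounding noise) and are resolved by a fair coin from the same RNG
  stream.

The Pocock–Simon comparators use the standard marginal criterion — the
hypothetical sum over factors of $|n_{T,k,l(k)} - n_{C,k,l(k)}|$ at the
subject's own levels, raw counts, equal factor weights — since the method
is cited rather than restated in the source literature. Permuted blocks
are implemented as urn draws over the remaining slots of the current
block, which is distributionally identical to drawing the block
permutation upfront; stratified randomization runs one such urn per
cross-classification cell, and a truncated final block simply stops with
the trial.

## What the simulator emulates

`trial_design()` / `simulate_trial()` reproduce the evaluation study's
data-generating process:

* Cohorts of $n = 20$ or 40 subjects; three factor scenarios (three
  binary, six binary, three polytomous with 5/4/3 levels).
* Binary factors: the non-reference prevalence is redrawn per replicate
  from Uniform(0.2, 0.8) — each simulated trial is a new population — with
  a fixed-prevalence mode available. Polytomous factors are equiprobable.
* Factor effects: each non-reference level's effect is drawn from
  Uniform$(0, 2\bar\beta)$, whose mean is the design's "average
  prognostic effect" $\bar\beta$; reference levels are 0 by definition.
  The interval is configurable via `effect_range`. $\bar\beta$ defaults
  to 1. Neither choice is consequential for the adjusted analysis: with
  every dummy in the model the treatment $t$ statistic is *exactly*
  invariant to the factor effects (they are projected out), and the test
  suite asserts bit-level equality of study metrics across $\bar\beta$
  values sharing a seed.
* Responses: $y_i \sim N(\alpha\,1[\text{arm}_i = T] +
  \sum_k \beta_{k, x_{ik}},\, 1)$, drawn after the whole allocation
  sequence from noise generated with the cohort (so allocators can be
  compared on identical noise).

What it does **not** emulate: correlated prognostic factors, continuous
covariates, time trends in recruitment, non-normal or heteroscedastic
responses, missing covariate values, and unequal target allocation
ratios. Passing tests therefore certify the allocation algebra and the
operating characteristics under this idealized generating process, not
performance on any particular real trial.

## Analysis and evaluation conventions

Each simulated trial is analyzed by OLS of the response on the treatment
indicator plus all non-reference dummies, with the model-based variance
$\hat\sigma^2[(X'X)^{-1}]_{zz}$ and a two-sided $t$ test on $n - p$
degrees of freedom. Dummies for levels unobserved in a cohort are dropped
and flagged; replicates whose treatment column is collinear (all subjects
in one arm — impossible after burn-in for the adaptive schemes, possible
for simple randomization at tiny $n$) are excluded from aggregation with
a logged count, which `run_study()` reports so its (empirically
negligible) rate stays visible.

One convention deserves emphasis. In the six-method comparison
(`method_comparison()`), each scheme is analyzed **adjusting for the
factors it balances**: the four covariate-balancing methods with the full
regression, simple and block randomization with the unadjusted difference
in means (`adjust = "balanced"`, overridable to `"all"` or `"none"`).
This is not a stylistic choice but a logical necessity for the comparison
to be informative: under full adjustment the $t$ statistic is exactly
invariant to the prognostic effects, so *every* scheme would appear
"stable" as $\bar\beta$ grows. The degradation of the non-balancing
schemes operates through covariate imbalance that their natural analysis
leaves uncorrected — that is the cost the comparison quantifies.

Predictability is summarized by two indices pooled as ratios of sums over
subjects and replicates: the probability that an allocation differs from
the previous one (Predictability-I) and the probability that it goes to
the currently smaller arm (Predictability-II). Subjects facing equal arm
totals have no "smaller" arm; they are excluded from the second index's
denominator by default (`tie_mode = "half"` credits them 0.5 — both
modes are implemented because the convention is not fixed by the
definition).

Randomness is organized as one master seed from which per-replicate
cohort seeds and allocation seeds are drawn separately; running two
studies with the same master seed but different allocators (as
`method_comparison()` and `q_sweep()` do) therefore pairs them on
identical cohorts, a substantial variance reduction for the ordering
claims.

## Problem sizes and numerical checks

The full evaluation uses 10,000 replicates per cell
(`scripts/acceptance.R`), at which scale the binomial standard error of a
rejection rate near 0.05 is about 0.002 and near 0.5 about 0.005. The
test suite exercises the same pipeline at its smoke profile of 2,000
replicates per Table-style cell (tolerance ±0.03), 10,000 replicates for
the variance-accuracy claims on two representative cells, and 5,000 for
the monotonicity and method-ordering comparisons, keeping the default
`R CMD check`-style run in the minutes rather than hours.

Degenerate inputs are handled explicitly rather than by chance: empty-arm
imbalance queries raise a typed burn-in error, perfect fits set
$\hat\sigma^2 = 0$ and give $p = 1$ for a zero estimate, single-replicate
studies report an undefined empirical variance, and serialization
(`write_trial_state()`) validates count/total/history consistency on
read so a resumed real trial cannot silently start from a corrupted
state.

## Known limitations

* Two arms with 1:1 target allocation only.
* The distributional imbalance treats factors marginally; joint
  (interaction) balance is not targeted — same as classical
  minimization.
* The predictability indices are proxies for selection-bias
  vulnerability, not a model of an adversarial investigator.
* Monte-Carlo results at 2,000-replicate smoke scale carry ±0.01–0.03
  binomial noise; conclusions at that scale are calibration checks, not
  precise reproductions.
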