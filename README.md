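# twowaymin

Covariate-adaptive treatment allocation for **small two-arm clinical
trials**, built around *two-way minimization* — an allocation scheme that
is simultaneously treatment-adaptive and covariate-adaptive — together
with five comparator randomization schemes and a Monte-Carlo engine for
evaluating all of them (bias, variance, type I error, power,
predictability of allocation).

It is aimed at trial statisticians who need to (a) allocate real
subjects sequentially, in real time, with a resumable trial state, and
(b) justify the chosen scheme with simulated operating characteristics.

## The method

At any point in the trial let $N_T$, $N_C$ be the arm totals and
$n_{T,kl}$, $n_{C,kl}$ the per-arm counts of level $l$ of prognostic
factor $k$. Two imbalances are tracked:

* arm-size imbalance $D_1 = |N_T - N_C|$;
* distributional imbalance $D_2 = \sum_k w_k D_k$ with
  $D_k = \sum_l |p_{T,kl} - p_{C,kl}|$, the L1 distance between the two
  arms' level-proportion vectors (weights $w_k$ default to 1).

After a short burn-in (simple randomization until both arms are
nonempty), each new subject triggers a Bernoulli draw with probability
$\pi(D_1) = 1 - (1-q)^{D_1}$ (default $q = 0.05$):

* with probability $\pi$ — **rule A1**: allocate to the smaller arm;
* otherwise — **rule A2**: allocate to the arm that would make the
  prospective $D_2$ (including this subject's own factor levels) smaller.

Ties fall to a fair coin. Since $\pi(0)=0$, a size-balanced trial decides
purely on covariates; a lopsided one is increasingly forced back toward
equal sizes. Both rules are comparison-based, so decisions are invariant
to monotone transformations of either imbalance.

Comparators: simple randomization, permuted blocks (size 4), stratified
permuted blocks, deterministic Pocock–Simon minimization, and biased-coin
minimization (coin probability 0.7). Analysis is OLS of the response on
treatment plus factor dummies, with a two-sided $t$ test.

## Worked example

Real-time allocation of twelve consecutively recruited subjects with
three prognostic factors, using the packaged example files:

```r
library(twowaymin)
subjects <- read.csv(system.file("extdata", "example_subjects.csv",
                                 package = "twowaymin"))
spec <- factor_spec(c(2, 2, 3), names = c("sex", "smoker", "stage"),
                    labels = list(c("female", "male"), c("no", "yes"),
                                  c("I", "II", "III")))
set.seed(20260929)
res <- allocate_sequence(subjects, allocator_config("two_way"),
                         spec = spec)
cbind(subjects, arm = res$arms)
#>       sex smoker stage arm
#> 1  female     no    II   C
#> 2    male     no     I   C
#> ...
#> 12   male    yes   III   T
print(res$state)
#> Trial state: 12 subject(s) (T = 7, C = 5), D1 = 2
#> Overall distributional imbalance D2 (L1): 0.6286
```

`write_trial_state(res$state, "state.json")` persists the trial between
subjects; the installed `exec/twowaymin` script does the same from a
shell (`twowaymin allocate --covariates subjects.csv --config cfg.json
--state state.json --out allocated.csv --state-out state.json`).

A Monte-Carlo study of the scheme's operating characteristics ($n = 40$,
three binary factors, treatment effect 1.0, 2,000 replicates):

```r
dsn <- trial_design(40, "three_binary", treatment_effect = 1,
                    replicates = 2000)
run_study(dsn, seed = 1)
#> Monte-Carlo study: two_way allocator, n = 40, three_binary factors,
#>   effect 1 (2000 replicates, 0 excluded)
#>   bias -0.0107 | var 0.1042 (mean estimated 0.1011) | rejection 0.8530 (SE 0.0079)
#>   predictability I 0.5070, II 0.5577 | mean final D1 3.10, D2 0.148
```

Read: the adjusted estimator is unbiased (−0.01 is well within
Monte-Carlo noise), its model-based variance estimate (0.1011) tracks the
empirical variance of the estimates (0.1042), power at effect 1.0 is
about 85%, and a would-be predictor guessing "the smaller arm next" is
right only ~56% of the time — far below deterministic minimization's
~70%. `q_sweep()` and `method_comparison()` run the corresponding
parameter-tuning and six-method comparison experiments under common
cohorts; `write_metrics()` saves any of these tables as commented CSV.

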