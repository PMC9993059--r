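# erurn

Bayesian nonparametric estimation of **bivariate survival distributions
from left-truncated right-censored (LTRC) paired lifetimes**, on the
non-negative integer grid.

## The problem

In prevalent-cohort and joint-lifetime studies (coupled annuitants,
patient pairs, paediatric cohorts) each pair `(X, Y)` of lifetimes is
observed only if both members survive past their entry times — a pair
enters the sample only when `T^X <= X` and `T^Y <= Y` — and follow-up
ends before death for many pairs, so lifetimes are right-censored at
`C = T + Δ`. Under *bivariate* left-truncation the familiar product-limit
(Kaplan–Meier / Lynden-Bell) estimator is no longer consistent for the
marginal laws, and the truncated stratum (pairs that never entered the
sample) biases every empirical summary.

## The model and the estimator

Dependence is modelled with a one-factor latent convolution

    X = A + B,   Y = A + C,     A, B, C independent, non-negative,

so that all dependence flows through the common component and
`Cov(X, Y) = Var(A) >= 0`. Each latent component (and the truncation
variables `T^X` and the entry lag `ε`, with `T^Y = T^X + ε`) carries a
**reinforced urn process** (discrete beta-Stacy) prior: urn `j` holds
`ω_j` green and `β_j` red ball mass with `β_j = c F0({j})`,
`ω_j = c (1 − F0(j))`, where `F0` is the prior guess and `c` the strength
of belief.

The **expectation-reinforcement (ER) algorithm** alternates

1. an EM **E-step**: conditional laws of `A`, `B`, `C` given every
   observed record (exact or censored in either coordinate), plus the
   conditional laws of all five variables given the truncation event,
   which imputes `M − n = n (1 − p)/p` phantom pairs where
   `p = P(T^X <= X, T^Y <= Y)`;
2. a **reinforcement M-step**: the maximum-likelihood urn ratios are
   blended with the prior urns,

       G_j = ω_j + r · Agg(j),   N_j = β_j + ω_j + r · Agg(j−1),

   where `Agg(j)` aggregates the conditional survival functions of the
   E-step and `r` is the reinforcement. `c → 0` recovers the pure EM
   (maximum-likelihood) fit; `r → 0` returns the prior; `β = ω = 0`
   with `r = 1` collapses the univariate machinery to the LTRC
   product-limit estimator.

The package also provides the univariate reinforced-urn posterior and its
conjugate update, an LTRC product-limit baseline, a rejection-sampling
simulator for paired LTRC designs, a computable bound `Ω_{y_M}` on the
error from cutting the infinite supports at `y_M` (zero at
`y_M = T^X_max + ε_max`), and Gompertz/Frank-copula reference models.

## Worked example

```r
library(erurn)

# reference Poisson design: A~Poi(40), B~Poi(20), C~Poi(25),
# T^X~Poi(70), eps~Poi(7)-5, Delta~Poi(2); 10^4 observed pairs
sim <- simulate_ltrc(poisson_example_recipe(seed = 11, n_observed = 1e4))
sim$obs
#> ltrc_data: 10000 pairs; censored X 73.2%, Y 83.7%; max x* 87, max y* 86
100 * sim$n_rejected / sim$n_candidates   # truncated percentage
#> [1] 83.96982

fit <- fit_er(sim$obs, poisson_example_priors(),
              er_config(r = 1e4, c = 1, tol = 1e-9, max_iter = 1e4))
window_moments(fit$model, c(45, 82, 49, 84))[c("mean_x", "mean_y", "corr")]
#> $mean_x
#> [1] 59.4433
#> $mean_y
#> [1] 64.0722
#> $corr
#> [1] 0.6757
```

The window `[45, 82] x [49, 84]` spans the exactly-observed values:
nonparametric estimates are only informative there, so summaries are
reported conditioned on it. The fitted window mean of `X` (59.44) sits
within sampling error of the generating model's window mean (60.29)
despite ~84% of candidate pairs being truncated away and ~66% of the
observed ones being censored in both coordinates; the plain product-limit
estimator applied per margin is visibly biased on the same data. The true
unconditional correlation is `Var(A)/sqrt(Var X · Var Y)` =
`40/sqrt(60·65)` ≈ 0.64.

A thin command-line wrapper over the same functions ships in
`inst/cli/erurn.R` (subcommands `simulate`, `fit`, `km`, `moments`,
`bound`, `copula-eval`).

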