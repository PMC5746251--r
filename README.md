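# searchvpl

Ideal-observer modelling of perceptual learning and transfer in orientation
search.

## What this package is for

In present/absent visual search for an odd-oriented line among uniform
distractors, two robust phenomena interact: the **search asymmetry** (an
oblique target among near-cardinal distractors is easier to find than the
reverse) and **visual perceptual learning** (sensitivity grows over training
days, and the improvement may or may not transfer when the target and
distractor orientations swap). `searchvpl` implements a Bayesian
ideal-observer model in which both effects — and the *asymmetry of
transfer* — follow from one assumption: the reliability of an orientation
representation depends on the orientation and improves with training, while
the decision rule itself never changes.

It is aimed at researchers in visual psychophysics and computational
modelling who want to simulate the observer, fit its variants to
session-level sensitivity data, and compare learning hypotheses.

## The model

Each of N display locations yields a Gaussian orientation measurement,
`x_i ~ N(s_T, σ_T²)` at the target location and `x_i ~ N(s_D, σ_D²)`
elsewhere. The optimal present/absent decision pools local log-likelihood
ratios:

    d_i = ½ log(σ_D²/σ_T²) − ½ [ (x_i − s_T)²/σ_T² − (x_i − s_D)²/σ_D² ]
    d   = log( (1/N) Σ_i exp(d_i) ),      respond "present" iff d > 0

Learning reduces each orientation's uncertainty exponentially over sessions,
`σ(t) = σ₀ (1 + e^(−τ t))`, and four nested variants differ in which
asymmetries they allow: **R** (orientation-specific σ, shared rate, 3
parameters), **L** (shared σ, role-specific rates, 3), **RL** (both, 4) and
**RLG** (rates independent per group, 6). Model d′ is estimated by
simulating experiments (4,000 trials, 50% prevalence); variants are fitted
to group-mean d′ trajectories by multi-start Nelder-Mead least squares with
common random numbers, compared by AICc, and evaluated by
leave-one-observer-out cross-validated r² against a noise ceiling.

## Worked example

```r
library(searchvpl)

# a synthetic cohort with the study design: 2 groups x 5 observers,
# 6 training days + orientation-transfer test, 540 trials/session
cohort <- simulate_cohort(cohort_spec(seed = 1))
round(group_means(cohort), 2)
#>                 D1   D2   D3   D4   D5   D6 OrTest
#> near-cardinal 1.01 1.76 2.35 2.89 2.98 3.34   3.31
#> oblique       1.29 2.13 2.59 2.79 3.20 3.24   2.69

fit <- fit_search_model(cohort, "RL", n_trials = 2000, n_starts = 5, seed = 1)
fit
#> Observer-model fit, variant RL (4 free parameters)
#> Fitted to 14 group-mean d' points (sessions D1, D2, D3, D4, D5, D6, OrTest)
#>
#> Coefficients:
#> sigma_cardinal  sigma_oblique     tau_target tau_distractor
#>         5.8332         6.8497         0.3957         0.7769
#>
#> SSE = 0.3491,  AICc = -39.23

nc <- noise_ceiling(cohort)
sprintf("noise ceiling: [%.2f, %.2f]", nc$lower, nc$upper)
#> "noise ceiling: [0.91, 0.94]"
```

The group means show the three signatures the model explains: the oblique
group starts ahead of the near-cardinal group (search asymmetry, 1.29 vs
1.01), both groups improve monotonically over days, and at the orientation
test the near-cardinal group holds its day-6 level (3.31 vs 3.34, transfer)
while the oblique group drops (2.69 vs 3.24, specificity). The fitted
uncertainties put the oblique orientation above the near-cardinal one
(6.85° vs 5.83°), with distractor learning about twice as fast as target
learning. The noise ceiling bounds the cross-validated r² any model could
reach given between-observer variability.

`summary(fit)` adds observed-vs-fitted tables and the per-session σ
trajectories; `plot(fit)` draws d′ against session per group;
`predict_transfer()` on a `sessions = "training"` fit gives out-of-sample
transfer predictions; `run_pipeline()` chains all stages (simulate → fit all
variants → AICc table → cross-validation → transfer prediction → JSON/CSV
report).

## Package layout

- `R/` — observer model (`simulate_display`, `local_llr`, `global_decision`,
  `decide`, `simulate_experiment`, `sensitivity_and_bias`), learning
  dynamics (`uncertainty_at`, `role_mapping`, `session_reliabilities`),
  fitting and evaluation (`fit_search_model`, `aicc`, `loo_cv`,
  `noise_ceiling`, `predict_transfer`), cohort generation
  (`simulate_cohort`) and the pipeline (`run_pipeline`).
- `src/` — the compiled per-trial decision loop (Rcpp).
- `vignettes/search-vpl-model.Rmd` — the model, its assumptions, numerical
  choices and limitations.
- `tests/testthat/` — unit, property and acceptance tests.
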