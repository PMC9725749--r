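---
title: "Damage and repair dynamics of binary health deficits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Damage and repair dynamics of binary health deficits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Aging health is commonly summarized by the frailty index (FI): the fraction
`f = n/N` of a fixed list of `N` binarized health deficits an individual
currently has. The FI confounds two distinct dynamical processes: *damage*
(0 to 1 transitions; susceptibility to damage is the complement of
robustness) and *repair* (1 to 0 transitions; resilience). Given repeated
observations of all `N` deficits per subject, the numbers damaged and
repaired between consecutive visits, `n_d(t_j)` and `n_r(t_j)`, are direct
summary measurements of these processes, linked to the FI by the exact
conservation identity `n(t_{j+1}) = n(t_j) + n_d(t_j) - n_r(t_j)`.

This package estimates age-dependent damage and repair rates from such
panels, couples them to mortality, decomposes the acceleration of FI growth
into robustness and resilience contributions, and measures the timescales
over which individual deficit states persist.

## The longitudinal rate model

Repair and damage are modeled as Poisson counts with per-available-item
rates: over an interval of length `dt` with `n` deficits present,

```
n_r ~ Poisson( n * lambda_r(t) * dt )
n_d ~ Poisson( (N - n) * lambda_d(t) * dt )
```

using rates held constant within each interval (evaluated at the interval
start, together with the interval-start FI — an explicit-Euler convention
that matches how the generator feeds the FI back into the rates). Rates are
positive via the Softplus link `log(1 + e^x)`, chosen over `exp` because it
is asymptotically linear: large linear predictors yield proportionally, not
exponentially, large rates, which keeps Poisson means stable.

For mouse cohorts, the linear predictor uses the standardized covariates
`(1, t, sex, treatment, f, a0)` plus sex/treatment/time interactions, with
subject-specific intercepts and time-slopes for both processes. The four
random effects share one covariance `Sigma = sigma Omega sigma` with an
LKJ(2) prior on the correlation matrix `Omega` and half-Cauchy(0,1) priors
on the SDs; sampling uses the non-centered parameterization to avoid the
funnel geometry at small cohort sizes. Priors are N(0,3) on intercepts and
N(0,1) on all other coefficients, with all covariates standardized to mean
0, SD 1 so that these scales are comparable (interactions are products of
standardized parents). Time is measured in months for mice and years for
humans; every rate is per that unit.

## The survival component (mice)

Mortality is modeled jointly with proportional hazards on the age axis:

```
h_i(t) = h0(t, sex) * exp( gamma . u_i(t) + gamma_r eta_r_i(t) + gamma_d eta_d_i(t) )
```

where `eta = softplus^{-1}(lambda)` are the link-scale rates,
`u = (1, sex, treatment, sex:treatment, f, a0)` standardized, and
`h0(t, sex)` is a sex-specific M-spline baseline: a simplex-weighted
combination of non-negative basis functions, each integrating to 1, with a
uniform Dirichlet(1) prior on the weights. The cumulative hazard between
observed visits (and from the last visit to death/censoring) is computed by
5-point Gauss–Legendre quadrature per segment, exact for polynomial hazards
to degree 9. Beyond the last visit the FI covariate is carried forward, so
the link-scale rate trajectories extrapolate linearly in `t`.

### Spline bases and knot counts

The baseline-hazard knots are placed at the minimum and maximum of the
last-follow-up ages plus 15 uniformly spaced quantiles from 0.05 to 0.95
(17 knots); the deficit-state survival model uses the minimum and maximum of
representative event times plus 30 quantiles from 0.1 to 0.9 (32 knots).
Quantiles are computed over the distinct times so that heavily tied,
grid-scheduled data cannot collapse interior knots onto each other. The
basis is the standard Ramsay order-3 (quadratic) M-spline construction with
full boundary multiplicity: `knots + 1` basis functions (18 and 33), each
integrating to 1, positive at the boundary knots. Boundary positivity
matters statistically: a construction whose basis vanishes at the span
edges forces the hazard to zero there and visibly biases early
state-survival upward on constant-hazard data, so it was rejected. Death
times falling exactly on the last knot are pulled inside the span by 1e-4
of its width for the hazard evaluation.

The human coefficient surfaces use quadratic (order-3) B-splines per axis
with distinct knots at the minimum, terciles and maximum of the observed
wealth and baseline-age values: 2 interior + 3 = 5 basis functions per axis,
matching the 5 x 5 coefficient grid of each surface. A 5-knot reading with
three interior quantiles would force 6 basis functions per axis and break
the 5 x 5 grid, so the tercile placement is the only internally consistent
choice.

## The human varying-coefficient model

Human panels are larger and more heterogeneous; linear effects of wealth and
baseline age are insufficient. The human model therefore lets the intercept,
sex, time, and sex-time coefficients vary smoothly over `(wealth, a0)`
via tensor-product B-spline surfaces `beta_k(w, a0) = sum_ij s_ij B_i(w)
B_j(a0)`, added to a linear design
`(1, t, sex, w, f, a0, sex:t, w:t, a0:t, sex:f, w:f, a0:f)`. Subjects get
correlated random intercepts only — no subject time-slopes, because with
short series those overfit (residual credible-interval coverage climbs
towards 0.99–1.00, the diagnostic reported by
`posterior_predictive_check()`). There is no survival component for humans.

Each 5 x 5 coefficient grid gets a 2D random-walk smoothing prior: the
corner cell is N(0,1); cells in the first row or column follow a one-sided
walk along their only available axis (the paper-level definition leaves
edges open; the one-sided walk is our choice); interior cells follow a
two-component *density mixture*
`p_w N(s[i-1,j], tau_w) + p_b0 N(s[i,j-1], tau_b0)` (read as a mixture
density, as written, not a sum of random variables). The direction weights
`(p_w, p_b0)` get a Dirichlet(1.5) prior, and the step scales `tau` get
half-Normal(0,1) priors — scales must be positive, so the stated N(0,1) is
truncated at zero. One `(tau_w, tau_b0, p_w)` set is shared by the four
surfaces of each process.

This model is deliberately overparameterized — constant shifts can move
between the fixed design and the surfaces — and is identified through the
priors. That produces posterior ridges; fits of this model mix more slowly
per draw than the mouse model and benefit from longer chains.

## Posterior computation

All three posteriors (mouse joint, human, deficit-state survival) are
written as unconstrained-parameter log densities (stick-breaking simplexes,
canonical-partial-correlation Cholesky factors with the LKJ density and
transform Jacobians, log-scale positive parameters) in C++ templates that
TMB differentiates. Sampling is by the package's own No-U-Turn sampler:
tree doubling with slice termination, divergence detection at an energy
error of 1000, dual-averaging step-size adaptation targeting acceptance 0.8
(`adapt_delta`), and a diagonal mass matrix estimated in doubling warmup
windows with step-size re-adaptation after each window. Chains are
deterministic given a seed. `split_rhat()` and `ess_basic()` provide the
convergence contract: fits fail loudly when split-Rhat exceeds 1.05 on a
fixed effect (configurable to warn for exploratory fits).

Default fit settings are 2 chains with 1000 warmup and 1000 retained
iterations — desk-scale defaults; production analyses should raise these
(the mouse analyses that motivated this package used 4 chains with
4000+6000 iterations, `adapt_delta` up to 0.95 and deep trees, which is
hours of computation).

## Derived quantities

From a fitted model, `rate_curve()` evaluates per-draw rate trajectories
for a covariate profile (reference covariates, random effects at zero, or a
named subject) and integrates the FI feedback ODE
`df/dt = (1 - f) lambda_d - f lambda_r` with classic RK4 on the requested
grid, so rates and FI are mutually consistent within each draw. On top of
the curve:

- `fi_derivative()`: `(1 - f) lambda_d - f lambda_r` pointwise;
- `rate_time_slope()`: the total time-derivative
  `dlambda/dt = (deta/dt + deta/df df/dt) * logistic(eta)`. The Softplus
  derivative is the logistic of the *link-scale predictor* `eta`; a
  formulation that evaluates the logistic at the rate itself is a notation
  slip, not a different model;
- `curvature_terms()`: the exact split of `d2f/dt2` into a damage
  (robustness) term `(1-f) dlambda_d/dt - f' lambda_d` and a repair
  (resilience) term `-(f dlambda_r/dt + f' lambda_r)`; the per-time
  posterior proportion of draws with `damage - |repair| < 0` is the
  Bayesian analogue of a p-value for robustness dominating the curvature;
- `posterior_spearman()`: per-draw Spearman correlation between the rate
  and the observed interval-start ages (observed ages rather than a uniform
  grid, so tied structure mirrors the data);
- `hazard_ratio_per_sd()`: `gamma_r`, `gamma_d` rescaled to a 1 SD increase
  of the link-scale rates, with the SDs computed across all
  subject-intervals at posterior-median parameters.

## Deficit-state survival

`extract_state_intervals()` turns the panel into interval- or
right-censored lifetimes of damaged and undamaged deficit states. Only
spells that *begin at an observed transition* are used; spells already in
progress at the first visit have unknown onset and are excluded. The state
clock starts at the first visit in the new state (the right edge of the
entry interval); since the entry time itself is interval-censored, a
midpoint-entry option is exposed for sensitivity analyses. Repeated spells
of the same subject and deficit are pooled as independent records — an
independence assumption the user should keep in mind.

The Bayesian model is `h(t) = exp(gamma0) sum_l a_l M_l(t)` with
Dirichlet(1, 32) on `a` and N(0,10) on `gamma0`, fitted separately per
state and group; the likelihood is `S(T)` for right-censored records and
`S(T_lower) - S(T_upper)` for interval-censored ones. Group contrasts use a
permutation generalized log-rank test: log-rank scores computed from the
pooled Turnbull NPMLE (self-consistency EM) and a permutation null over
group labels. The permutation form gives exact finite-sample validity
without asymptotic approximations. Knot quantiles use interval midpoints as
representative event times (a convention; censoring times for censored
records).

## The synthetic-cohort generator

`ground_truth()` + `simulate_cohort()` generate mouse-like cohorts with
known dynamics: 124 binary items (a 31-item fractional index expanded
4-fold), 10 monthly visits from a baseline age near 16 months (the
4-week assessment cadence of enalapril-style intervention studies), repair
rates around 0.23/month at baseline declining with age, damage rates around
0.04/month rising with age and FI — so the mean FI holds near 0.15 early
and accelerates upward late, as observed in aging mice — correlated subject
heterogeneity (SDs 0.3 for intercepts and 0.1 for slopes on the link scale,
with negative repair-damage coupling), and mortality from a
piecewise-constant baseline rising with age whose log-hazard loads
positively on the damage rate and negatively on the repair rate. Monthly
intervals keep `lambda * dt` at or below about 0.25, inside the Poisson
model's domain of validity; coarser schedules with these rates push the
per-item transition probabilities toward saturation, where both the
capped-Poisson and the Bernoulli generator diverge from the fitted
likelihood. `ground_truth_human()` +
`simulate_human_cohort()` give the ELSA-like analogue: 23 ADL/IADL items, 9
biennial waves, baseline ages 50–89, log-normal raw wealth stored as
`log(w_raw + mean(w_raw))`, no mortality. Where the study conditions do not
pin a value (heterogeneity SDs, baseline hazards, initial FI), the defaults
above were chosen once as field-realistic magnitudes and are not tuned.

Transitions are simulated **per item** as Bernoulli flips with the exact
exponential-interval probability `1 - exp(-lambda dt)`, so counts can never
exceed the available items and the panel is a valid stochastic process.
This is deliberately *not* the Poisson likelihood the models fit: the
Poisson form is its small-rate approximation, and the quantity the models
estimate from Bernoulli data is the discretized rate
`(1 - exp(-lambda dt))/dt`. At mouse-like repair rates
(`lambda dt ~ 0.2–0.5`) the gap biases link-scale intercepts by several
posterior SDs — visible, and worth knowing about, when interpreting
absolute rates from real panels with long intervals. Parameter-recovery
calibration of the fitting machinery therefore uses
`count_model = "poisson"`, which draws counts from the fitted models' own
likelihood (capped at the available items; at realistic rates the cap has
negligible probability). Age trends, sex/treatment contrasts and all
qualitative behavior are unaffected by the choice of mode.

Mortality is sampled by exact inverse-transform inversion of the piecewise
constant hazard; subjects alive at the last scheduled visit are
right-censored there, and visits after death are removed. One `set.seed()`
scope governs all draws in a fixed subject order, so a seed reproduces the
cohort byte-for-byte (a single sequential stream rather than per-subject
streams; the reproducibility contract is the same).

What the generator does *not* emulate: measurement error (so pruning rules
are exercised on clean data), deficit-specific rate heterogeneity (all
items share the subject's rates; real deficits differ widely, which is
exactly what the state-survival module measures on real data),
visit-schedule irregularity beyond what the user supplies, informative
dropout other than death, and recruitment effects in humans. Passing tests
on synthetic cohorts therefore validates the estimation machinery, not the
biological claims; those rest on the real panels.

## Test and verification scale

The test suite fits models at deliberately small problem sizes chosen once:
recovery checks use 4 replicate cohorts of 60 subjects with 2 chains of
250+250 iterations; the interval-censored oracle uses 500 records; log-rank
calibration uses 200 null replicates at 499 permutations; human-model
property checks use 30–40 subjects with short, depth-capped chains. These
sizes keep the full suite to desk scale while leaving the assertions at
their nominal thresholds (e.g. coverage >= 90%, type-I error inside the
exact binomial interval).

## Posterior predictive diagnostics

`posterior_predictive_check()` replicates counts from the fitted Poisson
model, reports observed versus replicated count distributions, a per-draw
Bayesian R-squared per outcome, and residual coverage computed from
*randomized* posterior-predictive quantiles — for discrete counts, raw 95%
interval coverage is conservative by construction (small counts are almost
always inside any 95% interval), whereas the randomized quantile is exactly
uniform under a well-specified model. Two caveats: coverage approaching
0.99–1.00 flags overfitting (the criterion that motivated dropping subject
time-slopes in the human model); and because the check reuses the fitting
data, it is mildly conservative whenever subject-level random effects are a
non-negligible fraction of the observation count — at desk-scale cohorts
expect coverage slightly above 0.95 even for a perfectly specified model,
with the nominal band emerging only when observations far outnumber
effective parameters.

## Known limitations

- Per-interval constant-rate approximation: both the models and the
  derived quantities inherit the interval-start convention; very long
  intervals blur fast dynamics (net counts only).
- The Bernoulli/Poisson discretization gap above.
- The human model's prior-identified overparameterization makes its
  posterior geometry ridge-like; expect high treedepths.
- The baseline hazard is supported between the first and last knot; hazard
  below the earliest last-follow-up age is structurally zero, which is
  appropriate for cohorts whose deaths all occur inside the knot span.
- The NPMLE-based log-rank scores treat pooled spells as independent.
- Wealth in humans is observational; rate-wealth associations are
  correlations, not intervention effects.
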