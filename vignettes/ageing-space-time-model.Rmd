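---
title: "A space-time hierarchical model for regional ageing rates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A space-time hierarchical model for regional ageing rates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the model it fits, the priors
and sampler it uses, the choices that were genuinely open, and what the
synthetic-data tests do and do not demonstrate.

## The model

The data are a complete region-by-year panel of counts: `y_it`, the
residents aged 65 and over, and `n_it`, the total residents, for regions
`i = 1..R` and years `t = 1..T`. The ageing rate `p_it = y_it / n_it` is
always derived from the counts, never stored. The three-layer hierarchical
model is

* **Data layer.** `y_it ~ Poisson(n_it * p_it * u_it)` with
  `u_it ~ Gamma(r, r)`. The latent multiplier has mean 1 and variance `1/r`,
  so marginally the counts are negative binomial: region-year cells carry
  extra-Poisson noise of relative standard deviation about `1/sqrt(r)`.
* **Process layer.**
  `log(p_it) = alpha + s_i + (b0*t + v_t) + (b1_i*t + b2_i*t^2/2) + eps_it`.
  The time covariate `t` is measured in years and centred at the panel
  midpoint (see *Numerical choices*). Setting the quadratic term to zero
  (`bstm_spec(quadratic = FALSE)`) recovers the classical linear-local
  variant; the quadratic term is the package's reason to exist, since the
  pair `(b1_i, b2_i)` — local speed and local acceleration of ageing growth
  — is what the four-quadrant classification maps.
* **Hyperparameter layer.** `s_i`, `b1_i` and `b2_i` each decompose as a
  spatially structured part with an intrinsic CAR prior over the
  queen-contiguity graph plus an unstructured iid normal part (the classical
  Besag-York-Mollié sum, not the reparameterised BYM2 — matching the
  original BYM construction). `v_t` has a first-order random-walk prior
  (the one-dimensional intrinsic CAR). `eps_it` is iid normal. Every
  standard deviation has a half-normal prior with scale 10, the
  weakly-informative choice recommended for hierarchical scale parameters;
  `alpha` and `b0` are flat.

Two modelling decisions here were open:

* **A single global `r`.** Indexing the divergence coefficient by cell gives
  one free dispersion parameter per observation, which is unidentifiable.
  The package uses one shared `r` with an exponential prior of mean 10.
* **Both noise channels are kept.** `u_it` and `eps_it` both model cell
  noise and are only weakly jointly identified; the printed model form keeps
  both, and either can be switched off
  (`bstm_spec(iid_noise = FALSE)`, `overdispersion = "none"`). Their
  *combined* magnitude is well identified; how the posterior splits it
  between `sigma_eps` and `r` is not, and users should not interpret the
  split.

## Sampler design

Inference is by adaptive Metropolis-within-Gibbs (`fit_bstm()`), two chains
by default, deterministic given the seed.

**Collapsing the multipliers.** The sampler does not alternate draws of
`u_it` with the other blocks: drawing `u_it` from its exact conditional
`Gamma(r + y_it, r + n_it exp(eta_it))` lets the multipliers absorb whatever
systematic signal the current state has not yet explained, after which the
spatial and trend blocks see no likelihood gradient — the chain stalls with
all structure shrunk to its prior. Because the Poisson-Gamma mixture is
exactly negative binomial with size `r`, the multipliers are integrated out
analytically and the sampler explores the collapsed posterior. The exact
conditional remains available (`bstm:::gibbs_update_u`) and is verified
against 1-D quadrature in the tests.

**Blocks.** `alpha`, `b0` and the tracked global quadratic `c2` move by
Gaussian random walks with flat priors. Structured (CAR) vectors move by
single-site random walks against their conditional normal prior (neighbour
mean, variance `sigma^2/m_i`); unstructured vectors and the cell noise move
by vectorised per-coordinate random walks, valid because their full
conditionals are independent given the rest. Positive scalars (`r`, all
standard deviations) move on the log scale with the Jacobian in the ratio.
Proposals for random effects are scaled by the current value of their own
hierarchical standard deviation, so step sizes stay calibrated as the
hierarchy tightens; the scale parameter itself is unchanged within such a
block, so the proposal remains symmetric.

**Interchange moves.** Three likelihood-invariant move families connect
ridges that single-site updates traverse slowly: (i) shift an unstructured
effect and compensate in `eps` (region-level vs cell-level noise); (ii)
shift `b0` or `c2` and absorb the complement into `v` (polynomial trend vs
random walk); (iii) transfer mass between the structured and unstructured
parts of a BYM pair. Each is accepted on the prior ratio alone.

**Adaptation and recentring.** Per-coordinate step sizes adapt toward an
acceptance rate of 0.44 by Robbins-Monro updates during burn-in and are
frozen afterwards, preserving detailed balance for the retained draws.
After every sweep the state is recentred: the means of `s`, `v`, `b1`, `b2`
are moved into `alpha`, `b0` and `c2` so the intrinsic-CAR sum-to-zero
constraints hold while every cell predictor is unchanged (to below 1e-12;
verified in the tests). `c2` exists only for this bookkeeping — the mean of
the `b2` field is a global quadratic term, which the printed model leaves
inside `b2` — and is reported alongside `b2` draws; the identified local
acceleration is `b2_i` after centring.

**Known mixing limits.** With 6,000-iteration chains the BYM variance-split
parameters (`sigma_s_struct` vs `sigma_s_unstruct`, and `sigma_eps` vs `r`)
can keep R-hat well above 1.1: these are the classically weakly identified
nuisance directions. The identified quantities the package reports —
`exp(s_i)`, `b1_i`, `b2_i`, fitted and forecast rates — converge and are the
ones checked for recovery and coverage. In the national variant `b0` and
`b1` are separately sampled but only their sum is identified; predictions
depend only on the sum.

## National variant, forecasting and validation

`fit_national()` is the same machinery with the spatial block removed and
scalar local trends:
`log(P_t) = alpha + (b0*t + V_t) + (b1*t + b2*t^2/2) + eps_t`.

`predict_rate()` extrapolates each posterior draw: polynomial trend at the
target year, `V_t` propagated forward as a random walk with that draw's
`sigma_v` (increment variance proportional to the horizon), fresh
`eps ~ N(0, sigma_eps)`. The forecast distribution therefore carries both
parameter uncertainty and forward process noise — the wider, more honest
choice, taken because the extrapolation mechanism for the random effect was
an open question. Intervals are central 95% quantiles of the exponentiated
draws.

`cross_validate()` holds out a set of observed years and refits on the
rest. Implementation: the panel keeps its full year grid and the held-out
cells simply contribute no likelihood, so the random walk bridges the gap
exactly as the model says it should (interior holdouts are bridged, trailing
holdouts extrapolated). The point prediction for a held-out year is the
posterior median of the noise-free rate
`exp(alpha + b0*t + v_t + b1*t + b2*t^2/2)` — the mean-one noise channels
are excluded from point prediction. The error measure is RMSE in percentage
points, `sqrt(mean((100*(pred - obs))^2))`.

`policy_correct()` implements the birth-policy dilution: extra births do not
change the 65+ head-count over the forecast horizon, so the adjusted rate is
`rate * (pop_total_with_policy - pop_increase) / pop_total_with_policy`.
Applied to a 14.76% unadjusted forecast with a 1.45-billion with-policy
population and a 94-million policy-induced increase, it gives 13.80% (and
11.24% from the 12.02% interval bound). The function takes the with-policy
total and the increase as separate arguments so the implied no-policy total
(their difference) is explicit.

## Descriptive layer

`morans_i()` uses binary queen contiguity row-standardised before the
statistic is formed — the dominant convention. Constant vectors are an
error (the statistic is undefined), and the permutation expectation
`-1/(N-1)` is verified by Monte Carlo in the tests.
`average_annual_growth()` takes the number of compounding periods
explicitly: for a 1992-to-2015 comparison both 23 (intervals) and 24 (years)
conventions occur in practice; the documented replication of a 6.08% to
10.47% rise at 2.29% a year uses 24. `boxplot_stats()` follows the Tukey
convention (hinges, 1.5 IQR whiskers). Study-period staging (e.g.
1992–1999 / 2000–2010 / 2010–2015) is configuration, not code: `stage_fit()`
takes any list of year windows, which may share a boundary year.

## The synthetic generator

`simulate_panel()` draws panels from the model's own generative process at
fixed, known parameters (`default_truth()`), so recovery is testable without
any external data. The presets are calibrated once, to the descriptive
magnitudes a provincial ageing panel of the 1992–2015 era would show, and
are not tuning knobs:

* `provincial`: 31 regions on the packaged China-like contiguity graph
  (degrees 1–8; the island province bridged to its nearest mainland
  neighbour), 24 years; `alpha` and `b0` set so the implied national rate
  moves from 6.0% to 10.5%; `exp(s_i)` spanning about 0.7–1.3; local speeds
  `b1_i` with sd 0.005 per year and accelerations `b2_i` with sd 0.001 per
  year squared (both centred); populations 3 to 80 million growing 0.2–1% a
  year; `r = 400` and `sigma_eps = 0.01`, i.e. about 5% relative cell noise.
* `national`: the single-unit analogue (about 1.2 billion people, growth
  0.7% a year, small positive global acceleration).
* `flat`: a degenerate constant-rate panel for closed-form checks.

What passing recovery tests show: on data *generated by the model*, the
sampler recovers the spatial pattern (Pearson r above 0.9 against truth),
local speeds (above 0.8) and accelerations (above 0.6), with 95% intervals
covering the true `b1_i` for at least 85% of regions, inside a two-chain
6,000-iteration budget. What they do not show: robustness to features real
yearbook panels have and the generator does not emulate — census-vs-survey
measurement-error differences between years, boundary and definition
changes, migration-driven shocks, or misspecified contiguity. Conclusions
about real data inherit the model's assumptions.

## Numerical choices and degenerate inputs

* Time is centred at the panel midpoint to decorrelate the linear and
  quadratic terms (`bstm_spec(time_centering = "none")` counts from the
  first year instead); whether the source analyses started `t` at 0 or 1 is
  unstated, so this is a documented convenience choice that affects only the
  parameterisation, not fitted rates.
* Intrinsic CAR densities are evaluated up to their rank-deficient constant
  with `-(n-1) log(sigma)` normalisation; identifiability comes from the
  recentring step.
* A predictor overflowing `exp` yields a `-Inf` log likelihood, never a
  crash; a non-finite sampler state aborts with an error (it indicates a
  bug, not data trouble).
* Exact zero posterior medians in the trend classification resolve to the
  "weak" / "weakening" side — conservative about declaring strong growth.
  Classification is by median sign (the mapped quantity is the point value);
  `prob_b1_pos` / `prob_b2_pos` are attached so users can impose a
  credibility cut-off such as 0.8 instead.
* Panels must be complete grids with consecutive years; the loaders name the
  offending cells otherwise. Isolated regions in the adjacency input are
  refused with an instruction to add the bridging edge explicitly — silent
  patching would make runs irreproducible.
* The toy used to validate the sampler against a brute-force grid posterior
  runs with the spatial, temporal, local and noise blocks disabled, leaving
  `alpha` as the only unknown; the same structural switches serve the
  national variant. With everything else on, no grid is feasible.
* Test problem sizes: the suite uses the two-chain 6,000/3,000 profile for
  the recovery fit, 7,000/1,000 for the reduced toy, and 5,000-draw chains
  for the R-hat reference points — sizes chosen so the full suite runs in a
  few minutes while keeping Monte-Carlo noise well inside the asserted
  tolerances.

## Limitations

* Proper CAR (rho < 1) and Leroux priors, and space-time interaction beyond
  the `b1/b2` construction, are out of scope.
* The package reads prebuilt adjacency (GAL or edge list); it does not
  derive contiguity from polygons, and draws no maps — the result tables
  join cleanly to any mapping workflow.
* The variance decomposition (structured vs unstructured, `eps` vs `u`) is
  reported but should not be interpreted; only the identified combinations
  are meaningful.
* Forecasts extrapolate a quadratic local trend; far horizons (beyond about
  half the fitted span) lean heavily on the model form, and the widening
  credible intervals say so.
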