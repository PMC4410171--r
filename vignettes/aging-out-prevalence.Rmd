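---
title: "From registry incidence to prevalence with an aging-out recursion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From registry incidence to prevalence with an aging-out recursion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incprev)
```

## The problem

National outpatient registries typically record *new* diagnoses per year,
starting whenever the registry was set up. Prevalence — how many people
currently live with the diagnosis — additionally depends on everyone
diagnosed before the registry existed and still inside the population of
interest. For childhood disorders such as ADHD the population of interest
is bounded by age: every year a fixed, observable fraction of the under-19
population turns 19 and leaves. That single, measurable outflow makes a
very simple demographic accounting model workable.

`incprev` operationalises that model for annual registry tables with
columns `year`, `new_cases`, `pop_under19`, `pop_19` (see
`?validate_registry`), with the Slovenian ADHD table 1997–2013 included as
`slovenia_adhd()`.

## Model and assumptions

All computation happens in rate space, per 100 000 persons aged ≤ 19:

* incidence rate `I(n) = 1e5 * new_cases(n) / pop_under19(n)`;
* aging-out proportion `G(n) = pop_19(n) / pop_under19(n)`.

Prevalence accumulates by the recursion

$$P(n) = P(n-1)\,(1 - G(n)) + I(n), \qquad P(n_0) = I(n_0),$$

whose closed form is the cohort sum
$P(n) = \sum_{m \le n} I(m) \prod_{j=m+1}^{n} (1 - G(j))$. The assumptions
are strong and explicit:

1. **Diagnosis is permanent** until exit: no remission, mortality or
   migration terms. For a disorder managed as chronic through adolescence
   this is the registry-faithful reading, but it makes `P` an estimate of
   *diagnosed* prevalence, not of true underlying prevalence.
2. **Aging out is the only exit**, at the population-average proportion
   `G(n)` — prevalent cases are assumed to have the same age distribution
   as the under-19 population. This is the least-verifiable assumption:
   an incidence wave concentrated in young children would age out more
   slowly than `G` implies.
3. **Incidence before the registry** follows one of four scenarios
   (`default_models()`), because `P(2012)` still remembers cohorts
   diagnosed before 1997. The spread across scenarios
   (`cross_model_summary()$rel_deviation_pct`, about 6.6% in 2012 for the
   Slovenian table) is the honest summary of that structural uncertainty.

### Order of operations within a year

The algebra of the recursion is a genuine modelling choice: one can remove
the aging-out fraction before or after adding the new cohort. We adopt
*outflow first, inflow second* — `P(n-1)(1-G(n)) + I(n)` — i.e. the year's
new diagnoses are not themselves subject to aging out in the year of
diagnosis. The alternative, `(P(n-1) + I(n))(1-G(n))`, differs by under 6%
here; we fixed the convention once, on the evidence that it reproduces the
published 2012 and 2020 headline estimates for the packaged table, and use
it everywhere.

### Scenario assembly

Each scenario's incidence series is: model-reconstructed rates from its
start year through the end of the fitting window, then the *observed* rates
afterwards (the plateau-era observations are never replaced by their mean
inside the recursion — smoothing them would change `P(2012)` by less than
the scenario spread but would discard real year-to-year signal). The linear
scenario is deliberately not extrapolated backwards below zero before the
first observed year; the zero-before-registry assumption of the `raw`
scenario applies to it as well. Exponential scenarios are extrapolated back
to their historical start years (defaults 1987 and 1980, when the modern
and the predecessor diagnostic constructs entered practice), where the
back-cast rate is a small seed (~2.8 per 100 000 in 1980 for the Slovenian
fit).

## Fitting choices

* **Linear family**: OLS of the rate on `t = year − t_origin`; `a`
  (intercept, per 100 000) is the fitted rate at the origin year, `b` the
  annual increment (per 100 000 per year).
* **Exponential family**: log-linear OLS — `lm(log(rate) ~ t)` with
  `A = exp(intercept)` (per 100 000) and rate constant `k` (per year).
  We use log-linear OLS, not nonlinear least squares on the natural scale,
  and report r² on the log scale, the scale on which the model is linear
  and the residuals are plausibly homoscedastic. `fit_incidence_trend()`
  refuses windows with non-positive rates rather than silently dropping
  them.
* **Reparameterization**: shifting `t_origin` by Δ multiplies `A` by
  `e^{−kΔ}` and leaves `k` unchanged; the test suite checks this exactly.
* **Plateau summary** (`plateau_stats()`): sample mean and SD of the annual
  rates over the plateau window, with a t-based 95% CI,
  `mean ± t(n−1, 0.975)·sd/√n`. With n = 9 years the t quantile matters: a
  normal-based interval would be visibly too narrow.
* **r² conventions**: computed as `1 − SSres/SStot` on the fitting scale; a
  zero-variance response (an exactly flat series) is fitted exactly by the
  intercept and gets r² = 1 by convention.

## Uncertainty propagation

The only quantified uncertainty is the plateau-era mean incidence. Its 95%
CI bounds are substituted for the incidence in every year from the plateau
window's first year onwards (including projected years), the recursion is
re-run twice, and the resulting trajectories are reported as
`ci_lower`/`ci_upper`. Pre-plateau incidence keeps its point value — the
plateau CI describes the stable era, not the rising phase. Monotonicity of
the recursion in the incidence input guarantees the bounds bracket the
point trajectory wherever the substitution binds. Not propagated: sampling
noise in the trend fits, in `G`, or in the population projection; the
scenario spread is reported separately rather than folded into the CI.

## Projection

`project_prevalence()` continues each scenario with incidence fixed at the
plateau mean and `G` fixed at the arithmetic mean of the last three
observed years (defaults chosen as the shortest window that smooths
single-year noise without reaching back into a different demographic
regime). Under these constants every trajectory rises monotonically toward
the fixed point `I/G` (≈ 1 460 per 100 000 for the Slovenian values) and
never overshoots it. The under-19 population is extended by
`project_population()` with a constant annual factor equal to the
*geometric* mean of the trailing year-over-year ratios — the natural mean
for a geometric growth model; with the packaged table the arithmetic mean
differs only in the sixth decimal, but the convention is fixed. Absolute
counts are formed at reporting time as `rate × population / 1e5`
(`rate_to_count()`), with display rounding (`round_display()`: rates to the
nearest 10, counts to the nearest 50) applied only in human-readable
output, never inside computations.

## The synthetic generator, and what passing tests show

`simulate_registry()` generates tables with exactly the structure the
analysis assumes: incidence rising as `A·e^{kt}` to a cut-year, a constant
plateau after it, Poisson-distributed annual case counts with expectation
`rate × pop/1e5`, a geometrically drifting under-19 population, and a
constant (optionally jittered) aging-out proportion. Defaults mirror the
Slovenian table's magnitudes: `true_A = 30`, `true_k = 0.141` per year,
plateau 77 per 100 000, population 492 000 declining 1.3% a year,
`g_level = 0.06`, and a final population-only year.

Because the generator *is* the model, passing tests demonstrate internal
correctness — the recursion equals its cohort-sum closed form, noiseless
end-to-end runs reproduce the analytic trajectory to numerical precision,
Poisson noise shrinks as 1/√pop, and `recovery_experiment()` centres on the
truth — not that real registries satisfy the assumptions. Real data feature
diagnostic drift, reporting delays and overdispersion, none of which the
generator emulates; a scenario spread computed on real data should be read
with that in mind. In `recovery_experiment()` the truth for the linear
parameters `a`, `b` (which the exponential-rise generator does not possess)
is defined as the fit to the noiseless table, i.e. the estimand of the
working linear model; generator-native truths are used for `A`, `k` and the
plateau mean.

## Numerical and degenerate-input conventions

* Validation errors name the offending year (gap, duplicate, negative or
  inconsistent count); tables need at least two rows, fits at least three
  usable years, plateau summaries at least two.
* Years with population data but no case count (a trailing registry year)
  are carried for `G` and population purposes and excluded from rate-based
  operations.
* `G` before the first observed year is frozen at the earliest observed
  value. Those early cohorts are almost entirely aged out by the reporting
  years, so the trajectory is insensitive to this fill; the test suite's
  property tests exercise the recursion under freely varying `G` schedules.
* A zero-width plateau CI collapses both bound trajectories onto the
  substituted point run; a two-identical-rate plateau window yields a
  degenerate (zero-width) CI rather than an error.

## Problem sizes used in the test suite

Property tests run the recursion on randomly drawn instances of 3–25 years,
steady-state checks on two-century horizons, the Poisson scaling check on
300 replicates per population size, and the parameter-recovery check on 500
Poisson replicates at a registry-scale population (400 000), recovering the
exponential rate constant to within 10%. These sizes were chosen so the
Monte-Carlo error of each check sits well below its assertion margin.

## Known limitations

* The CI understates total uncertainty (only plateau-mean sampling error is
  propagated), and the projected-era CI in particular is narrower than an
  interval that also carried forward trend-fit uncertainty would be.
* `G` applies the population-average exit rate to the diagnosed cohort
  (assumption 2 above).
* The four scenarios share the observed plateau, so the cross-scenario
  spread only measures uncertainty about the *pre-registry* era.
* Diagnosed prevalence is a lower bound on clinical prevalence wherever the
  disorder is underdiagnosed.
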