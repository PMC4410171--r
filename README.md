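# incprev

Estimating how many people *live* with a diagnosis when a national registry
only tells you how many were *newly* diagnosed each year is a recurring
problem in psychiatric epidemiology: registries often start recently, while
prevalence depends on every cohort diagnosed since the disorder entered
clinical practice. `incprev` implements a transparent solution for
child-and-adolescent disorders where the only exit from the modelled
population is turning 19 ("aging out"), and applies it to the Slovenian
national ADHD registry (1997–2013), which ships with the package.

## The model

For each calendar year *n*, with the annual incidence rate *I(n)* (per
100 000 persons aged ≤ 19) and the aging-out proportion
*G(n) = pop₁₉(n) / pop₍≤19₎(n)*, prevalence accumulates by the recursion

```
P(n) = P(n−1) · (1 − G(n)) + I(n),        P(n₀) = I(n₀),
```

equivalent to the cohort sum P(n) = Σₘ I(m) · Πⱼ₌ₘ₊₁..ₙ (1 − G(j)):
diagnosis is permanent until the cohort ages out (no remission, mortality or
migration terms). Because the registry starts mid-epidemic, the start year
*n₀* and the pre-registry incidence are unknown; four scenarios bracket
them:

| scenario  | incidence before/during the rising phase                 | start |
|-----------|----------------------------------------------------------|-------|
| `raw`     | observed rates only, zero before the registry            | 1997  |
| `linear`  | OLS line *I = a + b·t* over the rising phase             | 1997  |
| `exp1987` | log-linear fit *I = A·e^{k·t}* extrapolated back         | 1987  |
| `exp1980` | same, extrapolated to the earlier diagnostic construct   | 1980  |

After the rising phase (1997–2003 for the Slovenian table) all scenarios use
the observed rates; the 2004–2012 "plateau" era is summarised by its mean
and t-based 95% CI, which is propagated through the recursion to give
prevalence bounds. Forward projection holds incidence at the plateau mean,
fixes G at the mean of the last three observed years, and extends the
under-19 population by geometric growth.

## Worked example

```r
library(incprev)
reg <- slovenia_adhd()

fit_incidence_trend(reg, "exponential", window = c(1997, 2003))
#> <trend_fit: exponential, years 1997-2003>
#>   A = 30.36 (rate at 1997), k = 0.1409 per year
#>   r-squared = 0.9315 (log scale)

plateau_stats(reg, window = c(2004, 2012))
#>    mean    sd     n ci_lower ci_upper window_start window_end
#> 1  76.9  12.8     9     67.1     86.8         2004       2012

prev <- estimate_prevalence(reg, fit_window = c(1997, 2003),
                            plateau_window = c(2004, 2012))
cross_model_summary(prev, 2012)
#>    year n_models  mean   min   max rel_deviation_pct ci_lower ci_upper
#> 1  2012        4  745.  722.  771.              6.58     671.     812.

proj <- project_prevalence(prev, 2020)
cross_model_summary(proj, 2020)
#>    year n_models  mean   min   max rel_deviation_pct ci_lower ci_upper
#> 1  2020        4  996.  981. 1012.              3.19     882.    1105.

fold_report(proj, list(c(1997, 2012), c(1997, 2020)))
#>   model    from    to  fold
#> 1 exp1980  1997  2012  4.80
#> 2 exp1980  1997  2020  6.31
```

Reading the numbers: the annual incidence rate roughly doubled every five
years (k ≈ 0.14/yr) before stabilising near 77 per 100 000. Accumulated
through the recursion, the four scenarios agree to within ~7%: about 745
per 100 000 children and adolescents — roughly 2 950 people — lived with an
ADHD diagnosis in 2012, rising to just under 1 000 per 100 000 (about 4 050
people, given the projected population) by 2020, a 6.3-fold increase over
1997.

`plot_incidence()` and `plot_prevalence()` draw the scenario curves;
`simulate_registry()` and `recovery_experiment()` generate synthetic
registries with Poisson case counts and check that the whole pipeline
recovers known parameters. A thin command-line front end with
`fit` / `prevalence` / `project` / `simulate` subcommands lives at
`inst/cli/incprev.R`.

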