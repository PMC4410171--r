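# Independent oracles and fixture builders shared across tests.

# Brute-force cohort accounting: each year's incidence cohort is carried
# forward and shrunk by the aging-out proportion of every later year,
#   P(n) = sum_{m <= n} I(m) * prod_{j = m+1}^{n} (1 - G(j)).
# `inc` and `g` are vectors indexed by `years`.
cohort_sum_prevalence <- function(years, inc, g) {
  vapply(seq_along(years), function(n) {
    sum(vapply(seq_len(n), function(m) {
      surv <- if (m < n) prod(1 - g[(m + 1):n]) else 1
      inc[m] * surv
    }, numeric(1)))
  }, numeric(1))
}

# Registry whose recomputed incidence rate follows rate_fun(year) exactly
# (constant population, fractional case counts are fine for rate arithmetic).
registry_from_rates <- function(years, rate_fun, pop = 400000,
                                g_level = 0.06) {
  tibble::tibble(
    year = years,
    new_cases = rate_fun(years) * pop / 1e5,
    pop_under19 = pop,
    pop_19 = round(g_level * pop)
  )
}

# The nine plateau-era annual rates as printed (1 d.p.), used as an
# independent arithmetic cross-check of the full-precision plateau summary.
printed_plateau_rates <- c(85.1, 77.4, 75.2, 56.3, 84.7, 58.3, 76.0, 83.7,
                           95.8)
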