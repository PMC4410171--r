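test_that("recursion equals the brute-force cohort sum on random instances", {
  withr::local_seed(421)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    years <- 2000:(1999 + n)
    inc_vals <- runif(n, 0, 100)
    g_vals <- runif(n, 0.01, 0.3)
    inc <- tibble::tibble(model = "m", year = years, incidence = inc_vals)
    g <- tibble::tibble(year = years, g = g_vals)
    got <- run_recursion(inc, g)
    expect_equal(got$prevalence,
                 cohort_sum_prevalence(years, inc_vals, g_vals),
                 tolerance = 1e-12)
  }
})

test_that("initial condition and degenerate dynamics behave as designed", {
  years <- 2000:2050
  g <- tibble::tibble(year = years, g = 0.06)

  # constant incidence: monotone approach to the fixed point I/G
  inc <- tibble::tibble(model = "m", year = years, incidence = 77)
  P <- run_recursion(inc, g)$prevalence
  expect_equal(P[1], 77)
  expect_true(all(diff(P) > 0))
  expect_true(all(P < 77 / 0.06))
  gaps <- 77 / 0.06 - P
  expect_equal(gaps[-1] / gaps[-length(gaps)], rep(0.94, length(P) - 1),
               tolerance = 1e-10)

  # incidence switched off: geometric decay with factor (1 - G)
  inc0 <- dplyr::mutate(inc, incidence = ifelse(year > 2010, 0, incidence))
  P0 <- run_recursion(inc0, g)$prevalence
  tail_idx <- which(years > 2010)
  expect_equal(P0[tail_idx],
               P0[tail_idx[1] - 1] * 0.94^seq_along(tail_idx),
               tolerance = 1e-12)
})

test_that("recursion is linear and monotone in the incidence series", {
  withr::local_seed(99)
  years <- 1990:2012
  inc_vals <- runif(length(years), 0, 90)
  g <- tibble::tibble(year = years, g = runif(length(years), 0.04, 0.08))
  inc <- tibble::tibble(model = "m", year = years, incidence = inc_vals)
  P <- run_recursion(inc, g)$prevalence

  P3 <- run_recursion(dplyr::mutate(inc, incidence = incidence * 3), g)
  expect_equal(P3$prevalence, 3 * P, tolerance = 1e-12)

  bigger <- dplyr::mutate(
    inc, incidence = incidence + runif(length(years), 0, 10)
  )
  expect_true(all(run_recursion(bigger, g)$prevalence >= P))
})

test_that("recursion validates spans and coverage", {
  inc <- tibble::tibble(model = "m", year = c(2000, 2001, 2003),
                        incidence = 1)
  g <- tibble::tibble(year = 2000:2003, g = 0.05)
  expect_error(run_recursion(inc, g), "gaps")
  inc2 <- tibble::tibble(model = "m", year = 2000:2003, incidence = 1)
  expect_error(run_recursion(inc2, g[1:2, ]), "does not cover year 2002")
  expect_error(run_recursion(inc2, g, end_year = 2005), "does not cover 2005")
})

test_that("aging-out schedule uses observed ratios and backfills the edge", {
  g <- g_schedule(slovenia_adhd(), span = c(1980, 2013))
  expect_equal(round(g$g[g$year == 2005], 4), 0.0614)
  expect_equal(round(g$g[g$year == 2013], 4), 0.0513)
  expect_equal(g$g[g$year < 1997], rep(29946 / 491915, 17))
  expect_true(all(g$g > 0 & g$g < 1))
  expect_error(g_schedule(slovenia_adhd(), c(1997, 2020)), "observed span")
})

test_that("CI propagation brackets the point trajectory from the plateau on", {
  prev <- estimate_prevalence(slovenia_adhd(), fit_window = c(1997, 2003),
                              plateau_window = c(2004, 2012))
  era <- prev[prev$year >= 2004, ]
  expect_true(all(era$ci_lower <= era$prevalence + 1e-9))
  expect_true(all(era$ci_upper >= era$prevalence - 1e-9))
  expect_true(all(prev$ci_lower <= prev$ci_upper))

  # degenerate plateau interval collapses the bounds onto one trajectory
  inc <- attr(prev, "incidence")
  g <- attr(prev, "g")
  plat <- attr(prev, "plateau")
  plat$ci_lower <- plat$mean
  plat$ci_upper <- plat$mean
  point <- run_recursion(inc, g, 2012)
  degen <- propagate_ci(point, inc, g, plat)
  expect_equal(degen$ci_lower, degen$ci_upper)
})

test_that("cross-model summaries aggregate point estimates", {
  prev <- tibble::tibble(
    model = rep(c("a", "b"), each = 3),
    year = rep(2010:2012, 2),
    prevalence = c(10, 20, 30, 10, 20, 30)
  )
  s <- cross_model_summary(prev, 2012)
  expect_equal(s$mean, 30)
  expect_equal(s$rel_deviation_pct, 0)
  expect_error(cross_model_summary(prev, 2013), "not covered")
  expect_error(cross_model_summary(prev[-6, ], 2012), "missing from model")
})

test_that("rates convert to counts and display rounding is conventional", {
  expect_equal(rate_to_count(1e5, 394681), 394681)
  expect_equal(rate_to_count(0, 1000), 0)
  expect_equal(rate_to_count(750, 394681), 750 * 394681 / 1e5)
  expect_equal(round_display(2940.7, 50), 2950)
  expect_equal(round_display(c(744, 996), 10), c(740, 1000))
  expect_error(rate_to_count(10, 0))
})
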