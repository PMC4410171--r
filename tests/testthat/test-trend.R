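test_that("linear fit recovers an exact line and degenerates sanely", {
  years <- 2000:2006
  reg <- registry_from_rates(years, function(y) 2 + 3 * (y - 2000))
  fit <- fit_incidence_trend(reg, "linear", window = c(2000, 2006))
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$slope, 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  flat <- registry_from_rates(years, function(y) rep(40, length(y)))
  flat_fit <- fit_incidence_trend(flat, "linear", window = c(2000, 2006))
  expect_equal(flat_fit$slope, 0, tolerance = 1e-10)
  expect_equal(flat_fit$intercept, 40, tolerance = 1e-10)
  expect_equal(flat_fit$r_squared, 1)
})

test_that("exponential fit recovers an exact curve and a flat series", {
  years <- 2000:2006
  reg <- registry_from_rates(years, function(y) 5 * exp(0.2 * (y - 2000)))
  fit <- fit_incidence_trend(reg, "exponential", window = c(2000, 2006))
  expect_equal(fit$intercept, 5, tolerance = 1e-10)
  expect_equal(fit$slope, 0.2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  flat <- registry_from_rates(years, function(y) rep(7, length(y)))
  flat_fit <- fit_incidence_trend(flat, "exponential", window = c(2000, 2006))
  expect_equal(flat_fit$intercept, 7, tolerance = 1e-10)
  expect_equal(flat_fit$slope, 0, tolerance = 1e-10)
})

test_that("shifting the time origin reparameterizes A but not k", {
  reg <- simulate_registry(noise = "none", population_only_last = FALSE)
  base <- fit_incidence_trend(reg, "exponential", c(1997, 2003),
                              t_origin = 1997)
  for (delta in c(-17, -10, 3)) {
    shifted <- fit_incidence_trend(reg, "exponential", c(1997, 2003),
                                   t_origin = 1997 + delta)
    expect_equal(shifted$slope, base$slope, tolerance = 1e-10)
    expect_equal(shifted$intercept, base$intercept * exp(base$slope * delta),
                 tolerance = 1e-10)
  }
})

test_that("fits refuse unusable windows", {
  reg <- slovenia_adhd()
  expect_error(fit_incidence_trend(reg, "linear", c(1997, 1998)),
               "insufficient data")
  expect_error(fit_incidence_trend(reg, "linear", c(2013, 2015)),
               "insufficient data")

  zero <- registry_from_rates(2000:2004, function(y) c(0, 10, 20, 30, 40))
  expect_error(fit_incidence_trend(zero, "exponential", c(2000, 2004)),
               "positive rates.*2000")
})

test_that("tidy and glance expose the fitted parameters", {
  fit <- fit_incidence_trend(slovenia_adhd(), "exponential", c(1997, 2003))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("A", "k"))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  gl <- generics::glance(fit)
  expect_equal(gl$nobs, 7L)
  expect_equal(gl$r.squared, fit$r_squared)
  expect_output(print(fit), "exponential")
})

test_that("plateau summary agrees with direct arithmetic on the printed rates", {
  plat <- plateau_stats(slovenia_adhd(), window = c(2004, 2012))
  expect_equal(plat$n, 9)
  # printed 1 d.p. rates are an independent route to the same statistics
  expect_equal(plat$mean, mean(printed_plateau_rates), tolerance = 0.001)
  expect_equal(plat$sd, sd(printed_plateau_rates), tolerance = 0.001)
  half <- qt(0.975, 8) * sd(printed_plateau_rates) / 3
  expect_equal(plat$ci_lower, mean(printed_plateau_rates) - half,
               tolerance = 0.01)
  expect_equal(plat$ci_upper, mean(printed_plateau_rates) + half,
               tolerance = 0.01)
})

test_that("plateau summary handles degenerate and undersized windows", {
  flat <- registry_from_rates(2000:2001, function(y) rep(50, 2))
  plat <- plateau_stats(flat, c(2000, 2001))
  expect_equal(plat$sd, 0)
  expect_equal(plat$ci_lower, plat$mean)
  expect_equal(plat$ci_upper, plat$mean)

  expect_error(plateau_stats(slovenia_adhd(), c(2012, 2013)),
               "insufficient data")
})

test_that("fold changes divide rates between years", {
  rates <- add_rates(slovenia_adhd())
  expect_equal(fold_change(rates, 1997, 2003), (329 / 424472) / (156 / 491915))
  expect_equal(fold_change(rates, 2005, 2005), 1)
  zero <- tibble::tibble(year = 1:2, incidence = c(0, 5))
  expect_error(fold_change(zero, 1, 2), "not positive")
  expect_error(fold_change(rates, 1990, 2000), "1990")
})
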