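#' Fit a trend model to the rising phase of an annual incidence rate
#'
#' Two families are supported, both fitted by ordinary least squares on
#' incidence rates computed from full-precision count ratios:
#'
#' * `"linear"` — `I(t) = a + b t`, fitted on the rate scale. `a` is the
#'   fitted rate (per 100 000) at `t = 0` and `b` the annual increase.
#' * `"exponential"` — `I(t) = A exp(k t)`, fitted as a log-linear model:
#'   OLS of `log(rate)` on `t`, with `A = exp(intercept)`. `k` is the rate
#'   constant (per year). The reported r-squared is on the log scale, the
#'   scale on which the model is linear.
#'
#' Time is measured as `t = year - t_origin`, so the intercept is the fitted
#' rate in the origin year (the first fitted year by default).
#'
#' @param registry A registry table (see [validate_registry()]).
#' @param family `"linear"` or `"exponential"`.
#' @param window Length-2 numeric, first and last calendar year of the fit.
#' @param t_origin Calendar year at which `t = 0`; defaults to `window[1]`.
#' @return A `trend_fit` object with [generics::tidy()], [generics::glance()],
#'   `predict()` and `print()` methods. `predict()` takes calendar years and
#'   returns fitted rates per 100 000.
#' @examples
#' fit <- fit_incidence_trend(slovenia_adhd(), "exponential", c(1997, 2003))
#' generics::tidy(fit)
#' predict(fit, years = 1980:1997)
#' @export
fit_incidence_trend <- function(registry,
                                family = c("linear", "exponential"),
                                window = NULL,
                                t_origin = NULL) {
  family <- match.arg(family)
  data <- add_rates(registry)
  if (is.null(window)) {
    window <- range(observed_years(data))
  }
  if (is.null(t_origin)) {
    t_origin <- window[1]
  }
  data <- dplyr::filter(data, .data$year >= window[1],
                        .data$year <= window[2], !is.na(.data$incidence))
  if (nrow(data) < 3) {
    stop("insufficient data: trend fit needs at least 3 years with case ",
         "counts in ", window[1], "-", window[2], call. = FALSE)
  }
  t <- data$year - t_origin
  if (family == "linear") {
    fit <- stats::lm(incidence ~ t, data = dplyr::mutate(data, t = t))
    intercept <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
  } else {
    if (any(data$incidence <= 0)) {
      stop("exponential fit requires strictly positive rates; year ",
           data$year[which(data$incidence <= 0)[1]], " has rate <= 0",
           call. = FALSE)
    }
    fit <- stats::lm(log(incidence) ~ t, data = dplyr::mutate(data, t = t))
    intercept <- exp(unname(stats::coef(fit)[1]))
    slope <- unname(stats::coef(fit)[2])
  }
  # coefficient of determination on the fitting scale; a zero-variance
  # response is fitted exactly by the intercept, so r2 = 1 by convention
  y <- stats::model.frame(fit)[[1]]
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= .Machine$double.eps * sum(y^2)) {
    1
  } else {
    1 - sum(stats::resid(fit)^2) / sst
  }
  structure(
    list(
      family = family,
      intercept = intercept,
      slope = slope,
      r_squared = r2,
      window = as.integer(window),
      t_origin = as.integer(t_origin),
      fit = fit
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  params <- if (x$family == "linear") {
    sprintf("a = %.4g (rate at %d), b = %.4g per year",
            x$intercept, x$t_origin, x$slope)
  } else {
    sprintf("A = %.4g (rate at %d), k = %.4g per year",
            x$intercept, x$t_origin, x$slope)
  }
  cat(sprintf("<trend_fit: %s, years %d-%d>\n  %s\n  r-squared = %.4f%s\n",
              x$family, x$window[1], x$window[2], params, x$r_squared,
              if (x$family == "exponential") " (log scale)" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(
    term = if (x$family == "linear") c("a", "b") else c("A", "k"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    intercept = x$intercept,
    slope = x$slope,
    r.squared = x$r_squared,
    window_start = x$window[1],
    window_end = x$window[2],
    t_origin = x$t_origin,
    nobs = stats::nobs(x$fit)
  )
}

#' @export
predict.trend_fit <- function(object, years, ...) {
  t <- years - object$t_origin
  if (object$family == "linear") {
    object$intercept + object$slope * t
  } else {
    object$intercept * exp(object$slope * t)
  }
}

#' Plateau summary of an incidence-rate series
#'
#' Sample mean, standard deviation and t-based 95% confidence interval of
#' the annual incidence rates over a window in which the rate fluctuates
#' around a constant level rather than trending. The interval is
#' `mean +/- t(n-1, 0.975) * sd / sqrt(n)` — the CI of the mean annual rate,
#' which is what gets propagated through the prevalence recursion.
#'
#' @inheritParams fit_incidence_trend
#' @param window Length-2 numeric, first and last calendar year of the
#'   plateau era.
#' @return A one-row tibble with columns `mean`, `sd`, `n`, `ci_lower`,
#'   `ci_upper`, `window_start`, `window_end` (rates per 100 000).
#' @examples
#' plateau_stats(slovenia_adhd(), window = c(2004, 2012))
#' @export
plateau_stats <- function(registry, window) {
  data <- add_rates(registry)
  rates <- dplyr::filter(data, .data$year >= window[1],
                         .data$year <= window[2],
                         !is.na(.data$incidence))$incidence
  n <- length(rates)
  if (n < 2) {
    stop("insufficient data: plateau statistics need at least 2 years with ",
         "case counts in ", window[1], "-", window[2], call. = FALSE)
  }
  m <- mean(rates)
  s <- stats::sd(rates)
  half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
  tibble::tibble(
    mean = m, sd = s, n = n,
    ci_lower = m - half, ci_upper = m + half,
    window_start = as.integer(window[1]),
    window_end = as.integer(window[2])
  )
}

#' Fold change between two years of a rate series
#'
#' @param data A tibble with a `year` column and one rate column (for
#'   example the output of [incidence_series()] or [estimate_prevalence()]
#'   filtered to one model).
#' @param year_from,year_to Calendar years; the result is
#'   `rate(year_to) / rate(year_from)`.
#' @param col Name of the rate column; by default the first of
#'   `"incidence"`, `"prevalence"` present in `data`.
#' @return A single ratio.
#' @examples
#' slovenia_adhd() |>
#'   add_rates() |>
#'   fold_change(1997, 2003)
#' @export
fold_change <- function(data, year_from, year_to, col = NULL) {
  if (is.null(col)) {
    col <- intersect(c("incidence", "prevalence"), names(data))[1]
    if (is.na(col)) {
      stop("no `incidence` or `prevalence` column found; supply `col`",
           call. = FALSE)
    }
  }
  if (length(unique(data$year)) != nrow(data)) {
    stop("`data` has repeated years; filter to a single model first",
         call. = FALSE)
  }
  pick <- function(y) {
    v <- data[[col]][data$year == y]
    if (length(v) != 1 || is.na(v)) {
      stop("year ", y, " not available in the series", call. = FALSE)
    }
    v
  }
  from <- pick(year_from)
  if (from <= 0) {
    stop("fold change undefined: rate in base year ", year_from,
         " is not positive", call. = FALSE)
  }
  pick(year_to) / from
}
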