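#' Annual aging-out schedule
#'
#' The aging-out proportion G is the annual fraction of the modelled
#' population (persons aged 19 or younger) that turns 19 and exits — the
#' only outflow in the prevalence model. Observed years use the registry's
#' `pop_19 / pop_under19`; years before the first observed year are filled
#' with the earliest observed proportion, which is all the back-extrapolated
#' incidence scenarios need (those early cohorts are mostly aged out by the
#' reporting years, so the fill choice has little leverage). Years after the
#' observed span are not filled here — forward projection sets its own
#' constant G (see [project_prevalence()]).
#'
#' @param registry A registry table.
#' @param span Length-2 numeric, first and last calendar year the schedule
#'   must cover. The end may not exceed the registry's last year.
#' @return A tibble with columns `year`, `g` covering `span`.
#' @examples
#' g_schedule(slovenia_adhd(), span = c(1980, 2013))
#' @export
g_schedule <- function(registry, span) {
  data <- add_rates(registry)
  if (span[2] > max(data$year)) {
    stop("aging-out schedule requested beyond the observed span (",
         max(data$year), "); use project_prevalence() for forward years",
         call. = FALSE)
  }
  years <- span[1]:span[2]
  first <- min(data$year)
  g <- ifelse(years < first,
              data$g[data$year == first],
              data$g[match(years, data$year)])
  tibble::tibble(year = years, g = g)
}

#' Run the aging-out prevalence recursion
#'
#' Accumulates prevalence from annual incidence with the cohort recursion
#'
#' \deqn{P(n) = P(n-1) (1 - G(n)) + I(n), \qquad P(n_0) = I(n_0),}
#'
#' where `I` is the annual incidence rate, `G` the aging-out proportion and
#' `n_0` each scenario's start year (prevalence is zero before the first year
#' of nonzero incidence). Diagnosis is treated as permanent until exit by
#' aging out: no remission, mortality or migration terms. Everything is
#' computed in rate space (per 100 000 of the under-19 population), so no
#' pre-observation population counts are needed; absolute counts are derived
#' at reporting time with [rate_to_count()].
#'
#' @param incidence A long incidence tibble (`model`, `year`, `incidence`),
#'   as from [incidence_series()], each model's rows spanning its start year
#'   through `end_year` with no gaps.
#' @param g An aging-out schedule tibble (`year`, `g`) covering every year of
#'   every model, as from [g_schedule()].
#' @param end_year Last year to compute; defaults to the last year present in
#'   `incidence`.
#' @return A long tibble `model`, `year`, `prevalence` (per 100 000).
#' @examples
#' inc <- incidence_series(slovenia_adhd(), fit_window = c(1997, 2003))
#' g <- g_schedule(slovenia_adhd(), span = c(1980, 2012))
#' run_recursion(inc, g)
#' @export
run_recursion <- function(incidence, g, end_year = max(incidence$year)) {
  g_of <- function(years) {
    v <- g$g[match(years, g$year)]
    if (anyNA(v)) {
      stop("aging-out schedule does not cover year ",
           years[which(is.na(v))[1]], call. = FALSE)
    }
    v
  }
  one <- function(df) {
    df <- dplyr::arrange(df, .data$year)
    df <- dplyr::filter(df, .data$year <= end_year)
    if (nrow(df) == 0 || max(df$year) < end_year) {
      stop("incidence series for model '", df$model[1],
           "' does not cover ", end_year, call. = FALSE)
    }
    if (any(diff(df$year) != 1)) {
      stop("incidence series for model '", df$model[1],
           "' has year gaps", call. = FALSE)
    }
    P <- numeric(nrow(df))
    P[1] <- df$incidence[1]
    if (nrow(df) > 1) {
      gv <- g_of(df$year[-1])
      for (i in 2:nrow(df)) {
        P[i] <- P[i - 1] * (1 - gv[i - 1]) + df$incidence[i]
      }
    }
    tibble::tibble(model = df$model[1], year = df$year, prevalence = P)
  }
  incidence |>
    dplyr::group_split(.data$model) |>
    purrr::map(one) |>
    purrr::list_rbind()
}

#' Propagate the plateau incidence CI through the recursion
#'
#' Re-runs the prevalence recursion twice per scenario, substituting the
#' lower (respectively upper) 95% confidence limit of the plateau-era mean
#' incidence rate for the incidence in every year from `from_year` onward.
#' Pre-plateau incidence keeps its point value: the plateau CI describes the
#' stable-era mean, not the rising phase. Because the recursion is monotone
#' in the incidence series, the two trajectories bound the effect of
#' plateau-mean uncertainty on prevalence.
#'
#' @param prevalence Point-estimate trajectories from [run_recursion()].
#' @param incidence The incidence tibble the trajectories were computed from.
#' @param g The aging-out schedule used.
#' @param plateau A one-row tibble from [plateau_stats()].
#' @param from_year First year in which the plateau bounds replace the
#'   incidence; defaults to the plateau window start.
#' @return `prevalence` with columns `ci_lower`, `ci_upper` appended.
#' @export
propagate_ci <- function(prevalence, incidence, g, plateau,
                         from_year = plateau$window_start) {
  end_year <- max(prevalence$year)
  bound_run <- function(bound) {
    inc <- dplyr::mutate(
      incidence,
      incidence = ifelse(.data$year >= from_year, bound, .data$incidence)
    )
    run_recursion(inc, g, end_year)
  }
  lower <- bound_run(plateau$ci_lower)
  upper <- bound_run(plateau$ci_upper)
  prevalence |>
    dplyr::left_join(dplyr::rename(lower, ci_lower = "prevalence"),
                     by = c("model", "year")) |>
    dplyr::left_join(dplyr::rename(upper, ci_upper = "prevalence"),
                     by = c("model", "year"))
}

#' Estimate prevalence trajectories from a registry table
#'
#' The high-level pipeline: fit the trend models on the rising phase, build
#' the per-scenario incidence series, derive the aging-out schedule, run the
#' prevalence recursion for each scenario and propagate the plateau-era
#' incidence CI. See [run_recursion()] for the model.
#'
#' @param registry A registry table.
#' @param fit_window Years of the rising phase used to fit the trend models.
#' @param plateau_window Years of the stable era summarised by
#'   [plateau_stats()]; its CI drives the prevalence bounds.
#' @param models Scenario list, see [default_models()].
#' @param end_year Last year of the trajectories; defaults to the last year
#'   with observed case counts.
#' @param ci Compute the CI trajectories? (`TRUE` by default.)
#' @return A long tibble `model`, `year`, `prevalence`, `ci_lower`,
#'   `ci_upper` (rates per 100 000), with attributes `"incidence"` (the
#'   series used, carrying its `"fits"`), `"g"` (the schedule), `"plateau"`
#'   and `"registry"` for downstream projection.
#' @examples
#' prev <- estimate_prevalence(slovenia_adhd(),
#'                             fit_window = c(1997, 2003),
#'                             plateau_window = c(2004, 2012))
#' cross_model_summary(prev, 2012)
#' @export
estimate_prevalence <- function(registry,
                                fit_window,
                                plateau_window,
                                models = default_models(),
                                end_year = NULL,
                                ci = TRUE) {
  registry <- validate_registry(registry)
  if (is.null(end_year)) {
    end_year <- max(observed_years(registry))
  }
  inc <- incidence_series(registry, models, fit_window)
  g <- g_schedule(registry, span = c(min(inc$year), end_year))
  plateau <- plateau_stats(registry, plateau_window)
  prev <- run_recursion(inc, g, end_year)
  if (ci) {
    prev <- propagate_ci(prev, inc, g, plateau)
  }
  attr(prev, "incidence") <- inc
  attr(prev, "g") <- g
  attr(prev, "plateau") <- plateau
  attr(prev, "registry") <- registry
  prev
}

#' Summarise prevalence across model scenarios at one year
#'
#' The cross-scenario mean is the headline estimate; the relative deviation
#' `(max - min) / mean * 100` summarises how much the historical-incidence
#' assumption matters.
#'
#' @param prevalence A long prevalence tibble covering `year` for at least
#'   two models (CI columns optional).
#' @param year Calendar year to summarise.
#' @return A one-row tibble: `year`, `n_models`, `mean`, `min`, `max`,
#'   `rel_deviation_pct`, and `ci_lower`/`ci_upper` (cross-model means of the
#'   bound trajectories) when bounds are present.
#' @export
cross_model_summary <- function(prevalence, year) {
  rows <- prevalence[prevalence$year == year, ]
  if (nrow(rows) == 0) {
    stop("year ", year, " not covered by any prevalence series",
         call. = FALSE)
  }
  missing <- setdiff(unique(prevalence$model), rows$model)
  if (length(missing) > 0) {
    stop("year ", year, " missing from model(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    year = year,
    n_models = nrow(rows),
    mean = mean(rows$prevalence),
    min = min(rows$prevalence),
    max = max(rows$prevalence),
    rel_deviation_pct = 100 * (max(rows$prevalence) - min(rows$prevalence)) /
      mean(rows$prevalence)
  )
  if (all(c("ci_lower", "ci_upper") %in% names(rows))) {
    out$ci_lower <- mean(rows$ci_lower)
    out$ci_upper <- mean(rows$ci_upper)
  }
  out
}

#' Convert a rate per 100 000 to an absolute count
#'
#' @param rate Rate per 100 000 persons.
#' @param population Size of the population the rate refers to.
#' @return `rate * population / 1e5`, unrounded.
#' @seealso [round_display()] for the reporting convention.
#' @export
rate_to_count <- function(rate, population) {
  stopifnot(all(population > 0))
  rate * population / 1e5
}

#' Round for display
#'
#' Headline numbers are conventionally reported rounded — prevalence rates to
#' the nearest 10 per 100 000, case counts to the nearest 50. All internal
#' computation stays unrounded.
#'
#' @param x Numeric vector.
#' @param nearest Rounding grain.
#' @return `x` rounded to the nearest multiple of `nearest`.
#' @export
round_display <- function(x, nearest = 50) {
  round(x / nearest) * nearest
}
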