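#' Aging-out proportion assumed beyond the observed span
#'
#' The arithmetic mean of the observed aging-out proportions over the last
#' `window` registry years (population rows count even where case counts are
#' missing).
#'
#' @param registry A registry table.
#' @param window Number of trailing years to average (3 by default).
#' @return A single proportion.
#' @examples
#' project_g(slovenia_adhd()) # mean of 2011-2013
#' @export
project_g <- function(registry, window = 3) {
  data <- add_rates(registry)
  if (window < 1 || window > nrow(data)) {
    stop("`window` must be between 1 and the number of registry years",
         call. = FALSE)
  }
  mean(utils::tail(data$g, window))
}

#' Project the under-19 population by geometric growth
#'
#' Extends the registry's `pop_under19` to a horizon year with a constant
#' annual factor equal to the geometric mean of the year-over-year population
#' ratios across the last `window` observed years — the natural "mean growth
#' rate" for a geometric growth model.
#'
#' @param registry A registry table.
#' @param horizon_year Year to project to (beyond the registry's last year).
#' @param window Number of trailing years whose ratios define the growth
#'   factor (3 by default, i.e. 2 annual ratios).
#' @return A tibble `year`, `pop_under19` from the last observed year to
#'   `horizon_year`; attribute `"growth_factor"` holds the annual factor.
#' @examples
#' project_population(slovenia_adhd(), 2020)
#' @export
project_population <- function(registry, horizon_year, window = 3) {
  registry <- validate_registry(registry)
  last <- max(registry$year)
  if (horizon_year <= last) {
    stop("`horizon_year` must exceed the last observed year ", last,
         call. = FALSE)
  }
  if (window < 2 || window > nrow(registry)) {
    stop("`window` must span at least 2 registry years", call. = FALSE)
  }
  pops <- utils::tail(registry$pop_under19, window)
  factor <- exp(mean(log(pops[-1] / pops[-length(pops)])))
  years <- last:horizon_year
  out <- tibble::tibble(
    year = years,
    pop_under19 = registry$pop_under19[registry$year == last] *
      factor^(years - last)
  )
  attr(out, "growth_factor") <- factor
  out
}

#' Project prevalence trajectories forward
#'
#' Continues each scenario's recursion past the last observed year under two
#' stationarity assumptions: annual incidence fixed at the plateau-era mean
#' (or an explicit override) and the aging-out proportion fixed at the mean
#' of the last `g_window` observed years. The CI trajectories are continued
#' the same way with the plateau CI bounds as the constant incidence. With a
#' constant incidence `I` and constant `G`, every trajectory approaches the
#' fixed point `I / G` monotonically from below and never overshoots it.
#'
#' @param prevalence The result of [estimate_prevalence()] (its attributes
#'   carry the incidence series, aging-out schedule and plateau summary).
#' @param horizon_year Last projected year; must be at least the series' last
#'   year (equal leaves the series unchanged).
#' @param incidence Constant incidence rate per 100 000 assumed for projected
#'   years; defaults to the plateau mean.
#' @param g_window Trailing years averaged for the projected aging-out
#'   proportion (see [project_g()]).
#' @return The extended prevalence tibble, same columns and attributes as the
#'   input, plus attributes `"projected_g"` and `"projection_from"` (first
#'   projected year).
#' @examples
#' prev <- estimate_prevalence(slovenia_adhd(),
#'                             fit_window = c(1997, 2003),
#'                             plateau_window = c(2004, 2012))
#' proj <- project_prevalence(prev, 2020)
#' cross_model_summary(proj, 2020)
#' @export
project_prevalence <- function(prevalence, horizon_year,
                               incidence = NULL, g_window = 3) {
  inc <- attr(prevalence, "incidence")
  g <- attr(prevalence, "g")
  plateau <- attr(prevalence, "plateau")
  registry <- attr(prevalence, "registry")
  if (is.null(inc) || is.null(g) || is.null(plateau) || is.null(registry)) {
    stop("`prevalence` must come from estimate_prevalence(); its series ",
         "attributes are missing", call. = FALSE)
  }
  last <- max(prevalence$year)
  if (horizon_year < last) {
    stop("`horizon_year` must not precede the series end ", last,
         call. = FALSE)
  }
  if (horizon_year == last) {
    return(prevalence)
  }
  if (is.null(incidence)) {
    incidence <- plateau$mean
  }
  g_const <- project_g(registry, g_window)

  new_years <- (last + 1):horizon_year
  inc_ext <- dplyr::bind_rows(
    inc,
    tidyr::expand_grid(model = unique(inc$model), year = new_years) |>
      dplyr::mutate(incidence = incidence)
  )
  g_ext <- dplyr::bind_rows(g, tibble::tibble(year = new_years, g = g_const))

  out <- run_recursion(inc_ext, g_ext, horizon_year)
  if (all(c("ci_lower", "ci_upper") %in% names(prevalence))) {
    out <- propagate_ci(out, inc_ext, g_ext, plateau)
  }
  attr(out, "incidence") <- inc_ext
  attr(out, "g") <- g_ext
  attr(out, "plateau") <- plateau
  attr(out, "registry") <- registry
  attr(out, "projected_g") <- g_const
  attr(out, "projection_from") <- last + 1
  out
}

#' Fold changes of prevalence between reference years
#'
#' Reports `P(to) / P(from)` for a set of year pairs on one scenario's
#' trajectory (by default the exponential scenario with the earliest start,
#' the scenario with the smallest internal deviations).
#'
#' @param prevalence A long prevalence tibble (possibly projected).
#' @param year_pairs A list of length-2 numeric vectors `c(from, to)`, or a
#'   two-column data frame with columns `from`, `to`.
#' @param model Scenario name; default picks `exp<earliest year>` if present,
#'   otherwise the first model.
#' @return A tibble `from`, `to`, `fold`.
#' @examples
#' prev <- estimate_prevalence(slovenia_adhd(),
#'                             fit_window = c(1997, 2003),
#'                             plateau_window = c(2004, 2012))
#' fold_report(prev, list(c(1997, 2012)))
#' @export
fold_report <- function(prevalence, year_pairs, model = NULL) {
  if (is.null(model)) {
    exp_models <- grep("^exp[0-9]+$", unique(prevalence$model), value = TRUE)
    model <- if (length(exp_models) > 0) {
      exp_models[which.min(as.integer(sub("exp", "", exp_models)))]
    } else {
      unique(prevalence$model)[1]
    }
  }
  series <- dplyr::filter(prevalence, .data$model == !!model)
  if (nrow(series) == 0) {
    stop("model '", model, "' not present in `prevalence`", call. = FALSE)
  }
  if (is.data.frame(year_pairs)) {
    year_pairs <- purrr::map2(year_pairs$from, year_pairs$to, c)
  }
  purrr::map(year_pairs, function(p) {
    tibble::tibble(
      from = p[1], to = p[2],
      fold = fold_change(series, p[1], p[2], col = "prevalence")
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(model = model, .before = 1)
}
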