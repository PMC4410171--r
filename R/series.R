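#' Incidence model scenarios
#'
#' The default scenario set used throughout the package. Each scenario says
#' how annual incidence before and during the trend window is reconstructed;
#' after the window every scenario uses the observed rates:
#'
#' * `raw` — observed rates only, zero incidence assumed before the first
#'   observed year;
#' * `linear` — the linear trend fit replaces the observed rates inside the
#'   fit window; zero before the first observed year (the fitted line is not
#'   extrapolated backwards);
#' * `exp1987` / `exp1980` — the exponential trend evaluated back to a
#'   historical start year (by default 1987 and 1980, the years the ADHD and
#'   ADD diagnostic constructs entered the DSM), zero before it.
#'
#' @param exp_starts Integer vector of start years for exponential
#'   back-extrapolation scenarios; one scenario `exp<year>` is created per
#'   element.
#' @return A named list of scenario specs (`family`, `start_year`), suitable
#'   for the `models` argument of [incidence_series()] and
#'   [estimate_prevalence()]. `start_year = NA` means the first observed year.
#' @export
default_models <- function(exp_starts = c(1987L, 1980L)) {
  out <- list(
    raw = list(family = "raw", start_year = NA_integer_),
    linear = list(family = "linear", start_year = NA_integer_)
  )
  for (s in exp_starts) {
    out[[paste0("exp", s)]] <- list(family = "exponential",
                                    start_year = as.integer(s))
  }
  out
}

#' Assemble per-scenario annual incidence series
#'
#' Builds, for each scenario, the annual incidence rate series that feeds the
#' prevalence recursion: model-reconstructed rates from the scenario's start
#' year through the end of the fit window, then the observed registry rates
#' up to the last observed year. Incidence is zero before each start year by
#' construction, so the series simply begins there.
#'
#' @param registry A registry table.
#' @param models Scenario list as produced by [default_models()].
#' @param fit_window Length-2 numeric, years used to fit the trend models
#'   (the rising phase of the incidence rate).
#' @param t_origin Year at which the trend models' `t = 0`; defaults to
#'   `fit_window[1]`.
#' @return A long tibble with columns `model`, `year`, `incidence`
#'   (per 100 000). The fitted [fit_incidence_trend()] objects are attached
#'   as attribute `"fits"`, and `fit_window` as attribute `"fit_window"`.
#' @examples
#' incidence_series(slovenia_adhd(), fit_window = c(1997, 2003))
#' @export
incidence_series <- function(registry,
                             models = default_models(),
                             fit_window,
                             t_origin = fit_window[1]) {
  if (length(models) == 0) {
    stop("`models` must name at least one scenario", call. = FALSE)
  }
  data <- add_rates(registry)
  obs_years <- observed_years(data)
  first_obs <- min(obs_years)
  last_obs <- max(obs_years)
  observed <- stats::setNames(data$incidence[match(obs_years, data$year)],
                              obs_years)

  families <- unique(purrr::map_chr(models, "family"))
  unknown <- setdiff(families, c("raw", "linear", "exponential"))
  if (length(unknown) > 0) {
    stop("unknown model family: ", unknown[1], call. = FALSE)
  }
  fits <- purrr::map(
    stats::setNames(nm = setdiff(families, "raw")),
    \(fam) fit_incidence_trend(registry, fam, fit_window, t_origin)
  )

  one_model <- function(spec, name) {
    fam <- spec$family
    start <- spec$start_year
    if (is.na(start)) start <- first_obs
    if (!fam %in% c("raw", "linear", "exponential")) {
      stop("unknown model family: ", fam, call. = FALSE)
    }
    if (fam == "raw" && start < first_obs) {
      stop("raw scenario cannot start before the first observed year ",
           first_obs, call. = FALSE)
    }
    years <- start:last_obs
    inc <- purrr::map_dbl(years, function(y) {
      if (y > fit_window[2]) {
        v <- observed[as.character(y)]
        if (is.na(v)) stop("no observed rate for year ", y, call. = FALSE)
        unname(v)
      } else if (fam == "raw") {
        unname(observed[as.character(y)])
      } else {
        predict(fits[[fam]], years = y)
      }
    })
    tibble::tibble(model = name, year = years, incidence = inc)
  }

  out <- purrr::imap(models, one_model) |> purrr::list_rbind()
  attr(out, "fits") <- fits
  attr(out, "fit_window") <- as.integer(fit_window)
  out
}
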