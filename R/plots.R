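#' Plot observed and modelled annual incidence rates
#'
#' Observed registry rates as points with one line per model scenario,
#' mirroring the conventional incidence figure for this analysis (raw points,
#' linear and exponential model curves).
#'
#' @param incidence A long incidence tibble from [incidence_series()].
#' @param registry Optional registry table; when supplied, observed rates are
#'   overlaid as points.
#' @return A ggplot object.
#' @examples
#' inc <- incidence_series(slovenia_adhd(), fit_window = c(1997, 2003))
#' plot_incidence(inc, slovenia_adhd())
#' @export
plot_incidence <- function(incidence, registry = NULL) {
  p <- ggplot2::ggplot(incidence,
                       ggplot2::aes(x = .data$year, y = .data$incidence,
                                    colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Annual incidence rate per 100 000",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
  if (!is.null(registry)) {
    obs <- dplyr::filter(add_rates(registry), !is.na(.data$incidence))
    p <- p + ggplot2::geom_point(
      data = obs,
      mapping = ggplot2::aes(x = .data$year, y = .data$incidence),
      inherit.aes = FALSE, shape = 18, size = 2
    )
  }
  p
}

#' Plot prevalence trajectories across model scenarios
#'
#' One curve per scenario; if CI trajectories are present, the cross-model
#' band is drawn as a ribbon.
#'
#' @param prevalence A long prevalence tibble from [estimate_prevalence()] or
#'   [project_prevalence()].
#' @param ci Draw the CI ribbon when bounds are available? (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_prevalence <- function(prevalence, ci = TRUE) {
  p <- ggplot2::ggplot(prevalence,
                       ggplot2::aes(x = .data$year, y = .data$prevalence,
                                    colour = .data$model))
  if (ci && all(c("ci_lower", "ci_upper") %in% names(prevalence))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper,
                   fill = .data$model),
      alpha = 0.12, colour = NA
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Prevalence rate per 100 000",
                  colour = "Scenario", fill = "Scenario") +
    ggplot2::theme_minimal()
}
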