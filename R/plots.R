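#' Plot the total Theil index by year
#'
#' Line chart of the total Theil index of each resource over the years of a
#' report — the overall-inequality trend view.
#'
#' @param report an `analysis_report` whose Theil stage ran.
#' @return A ggplot object.
#' @export
plot_theil_trend <- function(report) {
  df <- theil_part(report, "trend")
  df <- dplyr::filter(df, .data$component == "T_total")
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$value,
                                   colour = .data$resource)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Year", y = "Theil index (nats)", colour = "Resource",
                  title = "Total Theil index of resource allocation") +
    ggplot2::theme_minimal()
}

#' Plot per-region within-group Theil series
#'
#' One line per region, faceted by resource — where inside each region the
#' inequality sits and how it moves.
#'
#' @inheritParams plot_theil_trend
#' @return A ggplot object.
#' @export
plot_region_theil <- function(report) {
  df <- theil_part(report, "regions")
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$T_j,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~resource, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Within-region Theil index (nats)",
                  colour = "Region",
                  title = "Regional Theil index of resource allocation") +
    ggplot2::theme_minimal()
}

#' Plot contribution-rate series
#'
#' Rates of each region plus the between-region component, faceted by
#' resource; within a year the rates sum to 1.
#'
#' @inheritParams plot_theil_trend
#' @return A ggplot object.
#' @export
plot_contribution_rates <- function(report) {
  df <- theil_part(report, "contributions")
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$rate,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~resource) +
    ggplot2::labs(x = "Year", y = "Contribution rate", colour = "Component",
                  title = "Contribution rates to the total Theil index") +
    ggplot2::theme_minimal()
}

theil_part <- function(report, part) {
  stopifnot(inherits(report, "analysis_report"))
  if (is.null(report$theil)) {
    stop_healtheil("report has no Theil stage (densities-only panel?)",
                   class = "healtheil_domain_error")
  }
  dplyr::bind_rows(report$theil[[part]], .id = "resource")
}
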