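#' Plot a polynomial trend fit
#'
#' Observed annual values as points with the fitted polynomial as a line;
#' an optional horizontal band marks the natural fluctuation zone
#' `[-threshold, +threshold]` around zero.
#'
#' @param object A `trend_fit`.
#' @param threshold Optional non-negative threshold for the fluctuation
#'   band.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.8) +
    ggplot2::labs(x = "Year", y = "Value",
                  subtitle = paste0("degree ", object$degree,
                                    ", MAE = ", signif(object$mae, 3)))
  if (!is.null(threshold)) {
    p <- p +
      ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                        ymin = -threshold, ymax = threshold, alpha = 0.15) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed")
  }
  p
}

#' Plot annual fluxes by compartment
#'
#' @param table Annual flux table from [annual_fluxes()].
#' @param species Species to show (default: SO4, NH4, NO3).
#' @param compartments Compartments to show.
#' @return A ggplot object, faceted by species.
#' @export
plot_annual_fluxes <- function(table, species = c("SO4", "NH4", "NO3"),
                               compartments = c("bulk", "throughfall",
                                                "seepage40")) {
  d <- dplyr::filter(table, .data$species %in% !!species,
                     .data$compartment %in% compartments)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$flux_mmol_ie_m2,
                                  colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$species), scales = "free_y") +
    ggplot2::labs(x = "Year",
                  y = expression(Flux ~ (mmol[IE] ~ m^-2 ~ yr^-1)),
                  colour = "Compartment")
}

#' Plot a sulfur storage trajectory
#'
#' Annual input-output deltas as bars with the cumulative remaining
#' fraction of the initial stock as a line on a secondary axis.
#'
#' @param storage Tibble from [storage_trajectory()].
#' @return A ggplot object.
#' @export
plot_storage_trajectory <- function(storage) {
  scale <- max(abs(storage$delta_ie)) / 100
  ggplot2::ggplot(storage, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$delta_ie), fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$remaining_fraction * scale),
                       colour = "firebrick", linewidth = 0.9) +
    ggplot2::scale_y_continuous(
      name = expression(Delta * S ~ (mmol[IE] ~ m^-2)),
      sec.axis = ggplot2::sec_axis(~ . / scale,
                                   name = "Remaining stock (%)")
    ) +
    ggplot2::labs(x = "Year")
}

#' Plot an annual proton budget
#'
#' Direct throughfall input and nitrogen-transformation load as stacked
#' areas, with the seepage output as a line.
#'
#' @param budget Tibble from [proton_budget()].
#' @return A ggplot object.
#' @export
plot_proton_budget <- function(budget) {
  long <- budget |>
    dplyr::select("year", "direct_input", "n_transformation_load") |>
    tidyr::pivot_longer(-"year", names_to = "component",
                        values_to = "load")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$load, fill = .data$component),
                       alpha = 0.8) +
    ggplot2::geom_line(data = budget,
                       ggplot2::aes(y = .data$seepage_output),
                       colour = "black") +
    ggplot2::labs(x = "Year",
                  y = expression(Proton ~ load ~ (mmol[IE] ~ m^-2 ~ yr^-1)),
                  fill = NULL)
}

#' Plot S/N ratios over time
#'
#' @param ratios A tibble with a `year` column and one or more ratio
#'   columns (e.g. the `sn_throughfall` element of a `budget_report`, or
#'   the output of [emission_sn_ratio()]).
#' @return A ggplot object.
#' @export
plot_sn_ratio <- function(ratios) {
  long <- tidyr::pivot_longer(ratios, -"year", names_to = "series",
                              values_to = "ratio")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$ratio,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "S/N ratio", colour = NULL)
}
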