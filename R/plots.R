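#' Diagnostic plot of a simulated or measured vial time series
#'
#' Total vial amount of each isotopologue against time, one panel per
#' species, replicates as separate lines; the default 4-15 h slope
#' window is shaded.
#'
#' @param data A [simulate_vial()]/[read_timeseries()] tibble.
#' @param window Slope window to shade, hours (NULL to omit).
#' @return A ggplot object.
#' @export
plot_timeseries <- function(data, window = c(4, 15)) {
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(
      x = .data$time_h, y = .data$total_umol,
      group = .data$replicate, colour = factor(.data$replicate)
    )
  )
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect",
      xmin = window[1], xmax = window[2], ymin = -Inf, ymax = Inf,
      alpha = 0.08
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(
      x = "Time (h)", y = "Total vial amount (µmol)",
      colour = "Replicate"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vial_sim <- function(object, ...) plot_timeseries(object, ...)

#' Bar chart of aggregated activities
#'
#' Mean activity per process with +/- 1 SD error bars, the standard
#' presentation for triplicate tracer assays.
#'
#' @param object An [estimate_activities()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.activity_result <- function(object, ...) {
  agg <- aggregate_replicates(object)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$activity, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$sd,
        ymax = .data$mean + .data$sd
      ),
      width = 0.15
    ) +
    ggplot2::labs(
      x = NULL,
      y = expression("Activity (mg N " * g^-1 * " " * h^-1 * ")")
    ) +
    ggplot2::theme_minimal()
}

#' Reactor operation overview plot
#'
#' Effluent nitrogen species and dissolved N2O against operation day.
#'
#' @param records A [simulate_reactor()]-style table.
#' @return A ggplot object.
#' @export
plot_reactor <- function(records) {
  long <- records |>
    tidyr::pivot_longer(
      dplyr::all_of(c(
        "effluent_nh4", "effluent_no2", "effluent_no3", "dissolved_n2o"
      )),
      names_to = "variable", values_to = "mg_n_l"
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$day, y = .data$mg_n_l,
    colour = .data$variable
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Day", y = expression("Concentration (mg N " * L^-1 * ")"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
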