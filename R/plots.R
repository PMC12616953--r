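#' Plot population-average traces with interquartile ribbons
#'
#' Mean signal over time per sensor with a 25th–75th percentile ribbon, the
#' standard visualization of biosensor population dynamics.
#'
#' @param traces Quantified tibble (one row per cell-frame).
#' @param col Signal column to plot (e.g. `"efa"` or `"efa_norm"`).
#' @return A ggplot object.
#' @export
plot_population_traces <- function(traces, col = "efa") {
  summarised <- traces |>
    dplyr::group_by(.data$sensor, .data$time_min) |>
    dplyr::summarise(
      mid = mean(.data[[col]], na.rm = TRUE),
      lo = stats::quantile(.data[[col]], 0.25, na.rm = TRUE),
      hi = stats::quantile(.data[[col]], 0.75, na.rm = TRUE),
      .groups = "drop"
    )
  ggplot2::ggplot(summarised,
                  ggplot2::aes(x = .data$time_min, y = .data$mid,
                               colour = .data$sensor, fill = .data$sensor)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Time (min)", y = col, colour = "Sensor",
                  fill = "Sensor") +
    ggplot2::theme_minimal()
}

#' Plot spectral products of an optical model
#'
#' Excitation (X) and emission (M) products per channel and fluorophore, the
#' integrands of the calibration ratios.
#'
#' @param products A [spectral_products()] tibble.
#' @return A ggplot object.
#' @export
plot_spectral_products <- function(products) {
  long <- tidyr::pivot_longer(dplyr::as_tibble(products), c("X", "M"),
                              names_to = "product", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$value,
                               colour = interaction(.data$channel,
                                                    .data$fluorophore,
                                                    sep = "/"))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~product, scales = "free_y") +
    ggplot2::labs(x = "Wavelength (nm)", y = "Spectral product (a.u.)",
                  colour = "channel/fluorophore") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Replicate-level characterization plot
#'
#' Per-sensor bars of the replicate-mean Signal, Noise and SNR with the
#' individual replicate means overplotted, mirroring the standard
#' characterization figure.
#'
#' @param object A `fret_characterization` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fret_characterization <- function(object, ...) {
  long <- tidyr::pivot_longer(object$replicates,
                              dplyr::any_of(c("signal", "noise", "snr")),
                              names_to = "metric", values_to = "value")
  group <- if ("sensor" %in% names(long)) "sensor" else NULL
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = if (is.null(group)) "" else .data$sensor, y = .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "col", alpha = 0.6,
                          ggplot2::aes(fill = if (is.null(group)) ""
                                       else .data$sensor)) +
    ggplot2::geom_jitter(width = 0.1, size = 1, colour = "grey30") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Replicate mean") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
  p
}
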