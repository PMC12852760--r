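## ggplot2 visualisation helpers.

#' Plot RF waveforms, decay curves and maps
#'
#' `autoplot()` methods: an `rf_shape` is drawn as amplitude (Hz) and
#' unwrapped phase (rad) panels over time; `decay_curves` as signal versus
#' train length by polarity; a `relax_map` as a raster of fitted relaxation
#' times.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name raffsim-autoplot
NULL

#' @rdname raffsim-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.rf_shape <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::tibble(time = object$time * 1e3,
                   `amplitude (Hz)` = object$amplitude / (2 * pi),
                   `phase (rad)` = object$phase),
    -"time", names_to = "channel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' @rdname raffsim-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.decay_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time * 1e3, y = .data$signal,
                                       colour = .data$polarity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "train length (ms)", y = "signal",
                  title = unique(object$method)[1]) +
    ggplot2::theme_minimal()
}

#' @rdname raffsim-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.relax_map <- function(object, ...) {
  df <- tidy.relax_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value * 1e3)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = "T (ms)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$method_label, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a simulated relaxation table
#'
#' Dot plot of fitted R and SS per method from
#' [simulate_relaxation_table()] output.
#'
#' @param tab tibble from [simulate_relaxation_table()].
#' @return A ggplot object.
#' @export
plot_relaxation_table <- function(tab) {
  df <- tidyr::pivot_longer(tab, c("R", "SS"), names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value,
                                   colour = .data$scenario)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
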