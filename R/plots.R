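#' Plot a simulated network trajectory
#'
#' Panels for free-barbed-end density, height, WH2 occupancy and the
#' cumulative fluxes over time.
#'
#' @param object A `sim_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_trajectory <- function(object, ...) {
  s <- object$samples |>
    tidyr::pivot_longer(
      c("free_ends", "height_um", "wh2_occupancy"),
      names_to = "observable", values_to = "value"
    )
  ggplot2::ggplot(s, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~observable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an exponential-decay fit over its data
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- tibble::tibble(
    x = seq(min(object$data$x), max(object$data$x), length.out = 200)
  )
  grid$y <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#d95f02") +
    ggplot2::labs(x = "load", y = "normalised rate") +
    ggplot2::theme_minimal()
}

#' Plot a donor-quench fit
#'
#' @param object A `quench_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quench_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$donor_intensity)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#d95f02") +
    ggplot2::labs(x = "time after quencher addition (s)", y = "donor intensity") +
    ggplot2::theme_minimal()
}

#' Plot a tether-force fit: data and model ratio versus stress
#'
#' @param object A `tether_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tether_fit <- function(object, ...) {
  d <- object$fitted
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$stress, .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$model_ratio), colour = "#d95f02") +
    ggplot2::labs(
      x = "growth stress (Pa)",
      y = "wt / bulky incorporation ratio"
    ) +
    ggplot2::theme_minimal()
  if ("error" %in% names(d)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$ratio - .data$error,
        ymax = .data$ratio + .data$error
      ),
      width = 0
    )
  }
  p
}

#' Plot per-network or per-filament rates versus load
#'
#' @param rates Tibble `stress`, `channel` and a rate column.
#' @param rate Column to plot (default `per_network_rate`).
#' @return A ggplot object.
#' @export
plot_rate_table <- function(rates, rate = "per_network_rate") {
  ggplot2::ggplot(
    rates,
    ggplot2::aes(.data$stress, .data[[rate]], colour = .data$channel)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "growth stress (Pa)", y = rate) +
    ggplot2::theme_minimal()
}
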