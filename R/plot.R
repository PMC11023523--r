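#' Quiver plot of a velocity-field frame
#'
#' Normalized direction arrows on the analysis grid, optionally overlaid
#' with detected defects (+1 circles, -1 diamonds, as in streamline figures
#' of monolayer velocity fields).
#'
#' @param field A velocity-field tibble (one frame).
#' @param defects Optional defect tibble for the same frame.
#' @param arrow_scale Arrow length as a multiple of the grid spacing.
#' @return A ggplot object.
#' @export
plot_field <- function(field, defects = NULL, arrow_scale = 0.8) {
  sp <- field_grid_of(field)$spacing
  speed <- sqrt(field$u_umph^2 + field$v_umph^2)
  len <- arrow_scale * sp
  df <- dplyr::mutate(field,
                      xend = .data$x_um + len * .data$u_umph / pmax(speed, 1e-12),
                      yend = .data$y_um + len * .data$v_umph / pmax(speed, 1e-12))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm")),
      linewidth = 0.3, color = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
  if (!is.null(defects) && nrow(defects) > 0) {
    d <- dplyr::mutate(defects, charge_lab = factor(.data$charge))
    p <- p + ggplot2::geom_point(
      data = d,
      ggplot2::aes(.data$x_um, .data$y_um, shape = .data$charge_lab,
                   color = .data$charge_lab), size = 3, stroke = 1.2) +
      ggplot2::scale_shape_manual(values = c(`-1` = 5, `1` = 1), name = "charge") +
      ggplot2::scale_color_manual(values = c(`-1` = "#d95f02", `1` = "#7570b3"),
                                  name = "charge")
  }
  p
}

#' Defect-count and order-metric time series
#'
#' Plots the defect counts together with mean speed and correlation length
#' from a pipeline metrics table, one panel per quantity.
#'
#' @param metrics The `metrics` tibble of a [run_pipeline()] result.
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(
    metrics[c("t_h", "n_total", "nu_umph", "xi_um")],
    -"t_h", names_to = "metric", values_to = "value")
  labs <- c(n_total = "defect count", nu_umph = "mean speed (µm/h)",
            xi_um = "correlation length ξ (µm)")
  long$metric <- factor(labs[long$metric], levels = unname(labs))
  ggplot2::ggplot(long, ggplot2::aes(.data$t_h, .data$value)) +
    ggplot2::geom_line(color = "#1b6ca8") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the normalized correlation and its exponential fit
#'
#' @param x A `velocity_correlation` (after [correlation_length()]).
#' @return A ggplot object.
#' @export
plot_correlation <- function(x) {
  df <- tidy(x)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$r_um, .data$c_norm)) +
    ggplot2::geom_point(color = "grey40") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, color = "grey60") +
    ggplot2::labs(x = "r (µm)", y = "C(r) / C(0)") +
    ggplot2::theme_minimal()
  if ("c_fit" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$c_fit), color = "#1b6ca8")
  }
  if (!is.null(x$xi_um) && !isTRUE(x$censored)) {
    p <- p + ggplot2::geom_vline(xintercept = x$xi_um, linetype = 3,
                                 color = "#1b6ca8")
  }
  p
}
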