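#' Plot a parameter-variation force sweep
#'
#' One force-length curve per parameter variation, over gray reference bands
#' at +/-10% and +/-20% of maximal isometric force.
#'
#' @param object An `mt_sweep` from [sweep_force_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mt_sweep <- function(object, ...) {
  bands <- dplyr::filter(object, .data$parameter == "f_iso_max_band")
  curves <- dplyr::filter(object, .data$parameter != "f_iso_max_band")
  band_ribbons <- tidyr::pivot_wider(
    dplyr::mutate(bands, band = abs(.data$variation), side = sign(.data$variation)),
    id_cols = c("l_norm", "band"), names_from = "side", values_from = "value",
    names_prefix = "s"
  )
  gg <- ggplot2::ggplot()
  for (b in sort(unique(band_ribbons$band), decreasing = TRUE)) {
    gg <- gg + ggplot2::geom_ribbon(
      data = band_ribbons[band_ribbons$band == b, ],
      ggplot2::aes(x = .data$l_norm, ymin = .data$`s-1`, ymax = .data$s1),
      fill = "grey50", alpha = if (b > 0.15) 0.15 else 0.3
    )
  }
  gg +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(
        x = .data$l_norm, y = .data$value,
        colour = factor(.data$variation), group = .data$variation
      )
    ) +
    ggplot2::labs(
      x = "baseline normalized fiber length",
      y = expression(F / F["iso,max"]),
      colour = paste0("variation of\n", attr(object, "which")),
      title = sprintf(
        "Isometric force under %s variation (a = %g)",
        attr(object, "which"), attr(object, "activation")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a normalized-sensitivity grid as a heatmap
#'
#' @param object An `mt_sensitivity_grid` from [sensitivity_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mt_sensitivity_grid <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$l_mt, y = .data$param_value, fill = .data$value)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "grey85", high = "red", midpoint = 0,
      na.value = "white"
    ) +
    ggplot2::labs(
      x = "MTU length (m)",
      y = attr(object, "which"),
      fill = "normalized\nsensitivity",
      title = sprintf(
        "Normalized dF/d(%s) x parameter / F_iso_max (a = %g)",
        attr(object, "which"), attr(object, "activation")
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mt_sweep
#' @param x An `mt_sweep` object.
#' @export
plot_sweep <- function(x, ...) autoplot.mt_sweep(x, ...)

#' @rdname autoplot.mt_sensitivity_grid
#' @param x An `mt_sensitivity_grid` object.
#' @export
plot_sensitivity_grid <- function(x, ...) autoplot.mt_sensitivity_grid(x, ...)
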