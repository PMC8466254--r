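# ggplot2 graphics for deviation cohorts and registration fits.

#' Box plots of implant deviations
#'
#' The standard accuracy-study figure: one box per deviation metric,
#' optionally split by a design factor. Distances and the angular deviation
#' are facetted on free scales (mm vs degrees).
#'
#' @param data A deviation tibble (see [measure_deviations()]).
#' @param by Optional factor column to split boxes by.
#' @param depth `"signed"` (default) or `"absolute"` depth values.
#' @return A ggplot object.
#' @export
plot_deviation_box <- function(data, by = NULL,
                               depth = c("signed", "absolute")) {
  depth <- match.arg(depth)
  metrics <- intersect(.metric_cols, names(data))
  data <- tibble::as_tibble(data)
  if (depth == "absolute" && "depth_mm" %in% metrics) {
    data$depth_mm <- abs(data$depth_mm)
  }
  long <- tidyr::pivot_longer(data[, c(by, metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = metrics)
  long$unit <- ifelse(long$metric == "angular_deg", "degrees", "mm")
  p <- if (is.null(by)) {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value))
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                       fill = .data[[by]]))
  }
  p + ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~unit, scales = "free") +
    ggplot2::labs(x = NULL, y = "deviation",
                  title = "Planned-versus-placed implant deviations") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Residual plot for a rigid registration
#'
#' Per-point fiducial residuals with the root-mean-square FRE as a reference
#' line.
#'
#' @param object A `rigid_registration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rigid_registration
#' @export
autoplot.rigid_registration <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$point),
                                  y = .data$residual_mm)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$fre_rms_mm, linetype = 2) +
    ggplot2::labs(x = "point pair", y = "residual (mm)",
                  title = sprintf("Registration residuals (FRE rms = %.3g mm)",
                                  object$fre_rms_mm)) +
    ggplot2::theme_bw()
}
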