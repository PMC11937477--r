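# ggplot2 graphics for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve with the Youden operating point
#'
#' @param object a `brw_roc` from [roc_youden()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.brw_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "red", size = 2.5) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.2f (%.2f-%.2f)", object$auc,
                      object$auc_ci[1], object$auc_ci[2]),
      subtitle = sprintf("Youden cutoff %.3g: Se %.0f%%, Sp %.0f%%",
                         object$cutoff, 100 * object$sensitivity,
                         100 * object$specificity)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' @param object a `brw_bland_altman` from [bland_altman()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.brw_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "blue") +
    ggplot2::geom_hline(yintercept = object$loa, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired readings",
                  y = "Difference (a - b)",
                  title = sprintf("Mean difference %.2f, LoA [%.2f, %.2f]",
                                  object$mean_diff, object$loa[1],
                                  object$loa[2])) +
    ggplot2::theme_minimal()
}

#' Plot a cross-section with detected wall boundaries
#'
#' @param section a `cross_section`.
#' @param measurement optional `wall_measurement` whose boundary polygons
#'   are overlaid.
#' @return A ggplot.
#' @export
plot_cross_section <- function(section, measurement = NULL) {
  ax <- section$axis_mm
  df <- tidyr::expand_grid(v = ax, u = ax)   # u varies fastest, as the matrix
  df$value <- as.vector(section$image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mm", y = "mm", fill = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(measurement) && measurement$status == "ok") {
    b <- measurement$boundary
    p <- p +
      ggplot2::geom_path(
        data = rbind(b[, c("x_inner", "y_inner")] |>
                       stats::setNames(c("x", "y")),
                     b[1, c("x_inner", "y_inner")] |>
                       stats::setNames(c("x", "y"))),
        ggplot2::aes(x = .data$x, y = .data$y), colour = "cyan",
        inherit.aes = FALSE) +
      ggplot2::geom_path(
        data = rbind(b[, c("x_outer", "y_outer")] |>
                       stats::setNames(c("x", "y")),
                     b[1, c("x_outer", "y_outer")] |>
                       stats::setNames(c("x", "y"))),
        ggplot2::aes(x = .data$x, y = .data$y), colour = "orange",
        inherit.aes = FALSE)
  }
  p
}

#' Plot per-group biomarker distributions
#'
#' @param cohort cohort tibble with `group` and a biomarker column.
#' @param var biomarker column name.
#' @return A ggplot.
#' @export
plot_group_comparison <- function(cohort, var = "brwall_t2_mis") {
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = .data$group, y = .data[[var]],
                               colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = var) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
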