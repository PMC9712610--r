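# ggplot2 figures for the main result types.

#' Plot the scale-free fit across candidate powers
#'
#' @param object A `soft_threshold`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot soft_threshold
#' @export
autoplot.soft_threshold <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$power, y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = object$target_r2, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), show.legend = FALSE) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "black")) +
    ggplot2::labs(x = "soft-threshold power",
                  y = expression("signed scale-free fit" ~ R^2)) +
    ggplot2::theme_minimal()
}

#' Plot sample PCA coordinates
#'
#' @param object A `sample_pca`.
#' @param design Optional sample design; points are coloured by population.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sample_pca
#' @export
autoplot.sample_pca <- function(object, design = NULL, ...) {
  df <- object$coords
  if (!is.null(design)) {
    df <- left_join(df, design[c("sample", "population")], by = "sample")
  }
  pct <- round(100 * object$var_explained[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(design)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$population), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}

#' Quadrant plot of missing-feature classification
#'
#' Expression vs identification frequency, coloured by region, with the
#' cutoff lines drawn at the region boundaries.
#'
#' @param quadrants Output of [quadrant_classify()].
#' @param expr_cutoff,freq_cutoff The cutoffs used (for the guide lines);
#'   defaults recompute the automatic cutoffs from the table.
#' @return A ggplot.
#' @export
plot_quadrants <- function(quadrants, expr_cutoff = NULL, freq_cutoff = NULL) {
  expr_cutoff <- expr_cutoff %||% median(quadrants$mean_log10_expr, na.rm = TRUE)
  freq_cutoff <- freq_cutoff %||% (max(quadrants$frequency) / 2)
  ggplot2::ggplot(quadrants,
                  ggplot2::aes(x = .data$mean_log10_expr, y = .data$frequency,
                               colour = .data$region)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = expr_cutoff, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = freq_cutoff, linetype = "dashed") +
    ggplot2::labs(x = "mean log10 expression (other layer)",
                  y = "identification frequency") +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heatmap
#'
#' @param stats A `module_stats`.
#' @return A ggplot.
#' @export
plot_module_trait <- function(stats) {
  stopifnot(inherits(stats, "module_stats"))
  df <- stats$module_trait
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population,
                                   y = factor(.data$module),
                                   fill = .data$cor)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$cor)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "matched population", y = "module",
                  fill = "eigengene-trait r") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
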