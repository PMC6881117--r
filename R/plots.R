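#' Plot descending single-cell expression curves
#'
#' @param curves Tibble from [expression_curves()].
#' @param log_y Show the value axis in log10 (zeros floored at
#'   `floor_value`).
#' @param floor_value Display floor for zero values (default 0.1).
#' @return A ggplot object.
#' @export
plot_expression_curves <- function(curves, log_y = TRUE, floor_value = 0.1) {
  df <- dplyr::mutate(curves, value = pmax(.data$value, floor_value))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$percentile,
                                        y = .data$value,
                                        colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cell population percentile", y = "expression",
                  colour = "gene") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a co-expression multiplicity histogram
#'
#' @param histogram Tibble (`n_genes`, `n_cells`), or a named list of them
#'   (e.g. per area) to juxtapose.
#' @return A ggplot object.
#' @export
plot_coexpression_histogram <- function(histogram) {
  if (!is.data.frame(histogram)) {
    histogram <- purrr::imap_dfr(histogram, function(h, nm)
      dplyr::mutate(h, group = nm))
  } else {
    histogram$group <- "all"
  }
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = factor(.data$n_genes), y = .data$n_cells,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "genes co-expressed per cell", y = "cells",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a type-expression profile
#'
#' Rows (genes) are normalized to their maximum and shown on a log10
#' pseudocolor scale, mirroring the neurotaxonomic heatmap display.
#'
#' @param object A `type_expression`.
#' @param floor Relative display floor (default 1e-4).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.type_expression <- function(object, floor = 1e-4, ...) {
  vals <- object$values
  mx <- apply(vals, 1, max)
  mx[mx == 0] <- 1
  rel <- pmax(vals / mx, floor)
  df <- tidy(structure(list(values = rel, statistic = object$statistic,
                            area = object$area, units = object$units),
                       class = "type_expression"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$leaf_type, y = .data$gene,
                                   fill = log10(.data$value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 rel. expr.") +
    ggplot2::labs(x = "neuron type", y = NULL,
                  title = sprintf("%s (%s)", object$area,
                                  object$statistic)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Heatmap of a peptidergic coupling matrix
#'
#' @param object An `np_coupling`.
#' @param ... Unused.
#' @return A ggplot object showing log10 coupling strength.
#' @export
autoplot.np_coupling <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_type,
                                   y = .data$source_type,
                                   fill = .data$log_value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 CPM·CPM") +
    ggplot2::labs(x = "target (receptor) type", y = "source (NPP) type",
                  title = sprintf("%s → %s (%s, %s)",
                                  object$pair$npp_gene,
                                  object$pair$npgpcr_gene,
                                  object$pair$galpha_family, object$area)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Faceted heatmaps of G-alpha family channels
#'
#' @param object An `np_channels`.
#' @param ... Unused.
#' @return A ggplot object with one facet per family.
#' @export
autoplot.np_channels <- function(object, ...) {
  df <- purrr::imap_dfr(object$channels, function(ch, f) {
    long <- as.data.frame.table(ch, responseName = "value",
                                stringsAsFactors = FALSE)
    names(long) <- c("source", "target", "value")
    long$family <- f
    long
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~family) +
    ggplot2::scale_fill_viridis_c(name = "normalized\ncoupling",
                                  limits = c(0, 1)) +
    ggplot2::labs(x = "target", y = "source",
                  title = sprintf("area %s, %s level", object$area,
                                  object$level)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot the distribution of per-cell resolution indices
#'
#' @param x An `np_ri_result` or `np_set_comparison`.
#' @return A ggplot object.
#' @export
plot_ri_distribution <- function(x) {
  if (inherits(x, "np_set_comparison")) {
    df <- purrr::imap_dfr(x$ri_results, function(r, nm)
      dplyr::mutate(r$per_cell, set = nm))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$ri)) +
      ggplot2::geom_violin(scale = "width") +
      ggplot2::stat_summary(fun = mean, geom = "point") +
      ggplot2::labs(x = NULL, y = "resolution index") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(x$per_cell, ggplot2::aes(x = .data$ri)) +
      ggplot2::geom_histogram(bins = 30) +
      ggplot2::labs(x = "resolution index", y = "cells") +
      ggplot2::theme_minimal()
  }
}
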