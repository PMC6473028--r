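#' Plot graph-metric curves across the sparsity sweep
#'
#' One panel per metric, one curve per group — the conventional display of
#' C, L, efficiencies and small-world indices against the sparsity threshold.
#'
#' @param curves Tidy tibble from [metric_curve()] (columns `group`,
#'   `sparsity`, `metric`, `value`).
#' @return A ggplot object.
#' @export
plot_metric_curves <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = 100 * .data$sparsity, y = .data$value,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Sparsity threshold (%)", y = "Metric value",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Heatmap of a partial-correlation matrix
#'
#' @param object A `pcor_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcor_matrix <- function(object, ...) {
  df <- tidy(object)
  lev <- colnames(object) %||% unique(c(df$roi_i, df$roi_j))
  df$roi_i <- factor(df$roi_i, levels = lev)
  df$roi_j <- factor(df$roi_j, levels = rev(lev))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_i, y = .data$roi_j,
                                   fill = .data$pcor)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Partial r",
                  title = sprintf("Group %s (n = %d)", attr(object, "group"),
                                  attr(object, "n_subjects"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a permutation comparison
#'
#' Observed metric difference across the sparsity grid with significant
#' sparsities marked.
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$sparsity,
                                   y = .data$obs_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$significant, ], colour = "red") +
    ggplot2::labs(x = "Sparsity threshold (%)",
                  y = sprintf("Difference in %s (%s - %s)",
                              attr(object, "metric"),
                              attr(object, "groups")[1],
                              attr(object, "groups")[2]),
                  title = sprintf("Permutation test (%d permutations); red = p < %g",
                                  attr(object, "n_perm"),
                                  attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}

#' Plot resampled hemispheric efficiencies
#'
#' Resampling distributions of left and right efficiencies per metric, with
#' the observed values marked.
#'
#' @param object An `asymmetry_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asymmetry_result <- function(object, ...) {
  d <- tidyr::pivot_longer(object$draws, c("M_L", "M_R"),
                           names_to = "side", values_to = "efficiency")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$side, y = .data$efficiency,
                                  fill = .data$side)) +
    ggplot2::geom_violin() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Network efficiency",
                  title = sprintf("Group %s: hemispheric efficiencies (sparsity %g%%)",
                                  object$group, 100 * object$sparsity)) +
    ggplot2::theme_minimal()
}

#' Bar plot of hub nodes
#'
#' Normalized betweenness per ROI with the hub threshold marked.
#'
#' @param hubs Tibble from [hub_table()] (optionally with a `group` column).
#' @param bi_threshold Threshold line (default 1.5).
#' @return A ggplot object.
#' @export
plot_hubs <- function(hubs, bi_threshold = 1.5) {
  df <- hubs[!is.na(hubs$bi) & hubs$bi > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$roi, .data$bi),
                                        y = .data$bi, fill = .data$hub)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = bi_threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Normalized betweenness (bi)") +
    ggplot2::theme_minimal()
  if ("group" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~group, scales = "free_y")
  }
  p
}
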