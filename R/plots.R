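#' Plot a partial-correlation network on a circle layout
#'
#' Nodes are placed on a circle grouped by community; edge width scales with
#' the absolute partial correlation, colour encodes the sign (solid-style
#' blue positive, red negative).
#'
#' @param object A `network_model`.
#' @param label_size Node label size.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.network_model <- function(object, label_size = 3, ...) {
  nodes <- object$node_names
  comm <- if (!is.null(object$communities))
    community_lookup(object$communities)[nodes] else rep("node", length(nodes))
  ord <- order(factor(comm, levels = unique(comm)))
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  pos <- tibble::tibble(node = nodes[ord], community = comm[ord],
                        x = cos(theta), y = sin(theta))
  ed <- tidy(object) |>
    dplyr::left_join(pos, by = c(node_a = "node")) |>
    dplyr::left_join(pos, by = c(node_b = "node"),
                     suffix = c("", "_b"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_b,
                   yend = .data$y_b, linewidth = abs(.data$weight),
                   colour = .data$weight > 0), alpha = 0.7) +
    ggplot2::geom_point(data = pos,
      ggplot2::aes(.data$x, .data$y, fill = .data$community),
      shape = 21, size = 8) +
    ggplot2::geom_text(data = pos,
      ggplot2::aes(.data$x * 1.18, .data$y * 1.18, label = .data$node),
      size = label_size) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166AC",
                                            `FALSE` = "#B2182B"),
                                 guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45)) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "community")
}

#' Lollipop plot of node centralities
#'
#' @param centrality_table Tibble from [centrality()].
#' @param value `"bei"` or `"ei"`.
#' @return A ggplot.
#' @export
plot_centrality <- function(centrality_table, value = c("bei", "ei")) {
  value <- match.arg(value)
  df <- centrality_table[!is.na(centrality_table[[value]]), ]
  df$node <- stats::reorder(df$node, df[[value]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[value]], y = .data$node,
                                   colour = .data$community)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data[[value]],
                                       yend = .data$node)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = toupper(value), y = NULL) +
    ggplot2::theme_minimal()
}

#' Permutation null distributions of a network comparison
#'
#' Histograms of the permuted global-strength difference and structure
#' statistic with the observed values marked.
#'
#' @param object A `network_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.network_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(stat = "global strength difference",
                   value = object$null$s_diff, observed = object$s_diff),
    tibble::tibble(stat = "structure statistic M",
                   value = object$null$m_stat, observed = object$m_stat))
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$observed),
                        colour = "#B2182B") +
    ggplot2::facet_wrap(~stat, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "permutation null", y = "count")
}

#' Bootstrap confidence-interval plot
#'
#' @param object An `edge_bootstrap`.
#' @param type Which quantities to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.edge_bootstrap <- function(object, type = c("edge", "ei", "bei"),
                                    ...) {
  type <- match.arg(type)
  df <- dplyr::filter(object$table, .data$type == !!type)
  df$entity <- stats::reorder(df$entity, df$estimate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$entity)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "estimate (95% percentile CI)", y = NULL)
}

#' Case-dropping stability plot
#'
#' Correlation between subsample and full-sample centralities across drop
#' proportions, with the r = 0.7 stability threshold.
#'
#' @param object A `stability_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_result <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(factor(.data$drop_proportion),
                               .data$correlation)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = object$cor_threshold,
                        linetype = 2, colour = "#B2182B") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "proportion of cases dropped",
                  y = paste0("correlation with full-sample ",
                             toupper(object$centrality)))
}
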