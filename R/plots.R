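#' Plot an estimated symptom network
#'
#' Draws the network at its Fruchterman-Reingold coordinates: edge width
#' proportional to |weight|, positive edges in green, negative in red
#' (the usual network-psychometrics palette), nodes labeled.
#'
#' @param object A `symptom_network`.
#' @param layout Optional precomputed [fruchterman_reingold()] tibble.
#' @param seed Layout seed when `layout` is not supplied.
#' @param label_size Node label size.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.symptom_network <- function(object, layout = NULL, seed = 1,
                                     label_size = 2.6, ...) {
  if (is.null(layout)) layout <- fruchterman_reingold(object, seed = seed)
  ed <- tidy(object)
  seg <- dplyr::left_join(ed, layout, by = c("from" = "node"))
  seg <- dplyr::rename(seg, x = "x", y = "y")
  seg <- dplyr::left_join(seg, layout, by = c("to" = "node"),
                          suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   linewidth = abs(.data$weight),
                   colour = .data$weight > 0),
      alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2e7d32",
                                            `FALSE` = "#c62828")) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 7, shape = 21, fill = "grey90") +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$node),
                       size = label_size, vjust = -1.6) +
    ggplot2::coord_equal(xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2)) +
    ggplot2::theme_void()
}

#' Plot standardized centrality profiles
#'
#' The classic centrality panel: z-standardized strength, expected
#' influence, closeness, and betweenness per node, one facet per index,
#' nodes ordered by strength.
#'
#' @param object A [centrality_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.centrality_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "node", dplyr::starts_with("z_")),
    cols = dplyr::starts_with("z_"),
    names_to = "index", values_to = "z", names_prefix = "z_")
  ord <- object$node[order(object$strength)]
  long$node <- factor(long$node, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$node)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(ggplot2::aes(group = .data$index)) +
    ggplot2::facet_wrap(~index, nrow = 1) +
    ggplot2::labs(x = "z-score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap edge-weight confidence intervals
#'
#' Edges ordered by point estimate, with the bootstrap interval band and
#' the replicate mean, mirroring the standard edge-accuracy panel.
#'
#' @param edge_ci A [bootstrap_edges()] tibble.
#' @param nonzero_only Drop pairs whose point estimate is zero.
#' @return A ggplot object.
#' @export
plot_edge_ci <- function(edge_ci, nonzero_only = TRUE) {
  df <- edge_ci
  if (nonzero_only) df <- dplyr::filter(df, .data$estimate != 0)
  df$edge <- paste0(df$from, "--", df$to)
  df$edge <- factor(df$edge, levels = df$edge[order(df$estimate)])
  ggplot2::ggplot(df, ggplot2::aes(y = .data$edge)) +
    ggplot2::geom_ribbon(ggplot2::aes(xmin = .data$lower,
                                      xmax = .data$upper,
                                      group = 1),
                         fill = "grey80") +
    ggplot2::geom_point(ggplot2::aes(x = .data$boot_mean), size = 0.6,
                        colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate), size = 0.8,
                        colour = "red") +
    ggplot2::labs(x = "edge weight", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Plot case-dropping stability curves
#'
#' Agreement rate (share of subsamples correlating at least 0.7 with the
#' full-sample index) against the drop proportion, one line per index,
#' with the CS thresholds 0.25 and 0.5 marked.
#'
#' @param cs A [cs_coefficient()] tibble (uses its `detail` attribute).
#' @return A ggplot object.
#' @export
plot_stability <- function(cs) {
  detail <- attr(cs, "detail")
  long <- tidyr::pivot_longer(detail, cols = -"drop",
                              names_to = "index", values_to = "agreement")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$drop, y = .data$agreement,
                                     colour = .data$index)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(0.25, 0.5), linetype = c(2, 3)) +
    ggplot2::labs(x = "proportion of cases dropped",
                  y = "P(cor with full sample ≥ threshold)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
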