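#' Plot per-edge importance along the transcript
#'
#' Simple positional view of edge-mask scores: each edge is drawn at the
#' midpoint of its endpoints, colored by edge type.
#'
#' @param scores Tibble from [learn_edge_mask()].
#' @param highlight Optional integer vector of 1-based positions to shade
#'   (e.g. a planted element's interval).
#' @return A ggplot object.
#' @export
plot_edge_importance <- function(scores, highlight = NULL) {
  df <- dplyr::mutate(scores, position = (.data$from + .data$to) / 2)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score,
                                        colour = .data$type)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "transcript position (nt)", y = "edge importance",
                  colour = "edge type") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::annotate("rect", xmin = min(highlight),
                               xmax = max(highlight), ymin = 0, ymax = 1,
                               alpha = 0.12)
  }
  p
}

#' Plot node-feature-group importance
#'
#' @param importance Tibble from [node_feature_importance()].
#' @return A ggplot bar chart of importance per encoding group and label.
#' @export
plot_feature_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = .data$group, y = .data$importance,
                               fill = .data$group)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "node-feature group", y = "mean probability drop") +
    ggplot2::theme_minimal()
}
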