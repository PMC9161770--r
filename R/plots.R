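#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_point geom_text
#'   geom_col geom_line labs theme_minimal scale_colour_brewer position_dodge
NULL

#' @export
ggplot2::autoplot

# concentric-ring layout: seed at the origin, neighbors on circles by depth
ring_layout <- function(nodes) {
  nodes |>
    group_by(.data$depth) |>
    mutate(angle = 2 * pi * (row_number() - 1L) / n()) |>
    ungroup() |>
    mutate(x = .data$depth * cos(.data$angle),
           y = .data$depth * sin(.data$angle))
}

#' Plot a neighborhood subgraph
#'
#' Nodes are placed on concentric rings by their distance from the seed;
#' edges are drawn as segments labelled implicitly by colour (evidence
#' source).
#'
#' @param object a `kg_subgraph` from [neighborhood()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot kg_subgraph
#' @export
autoplot.kg_subgraph <- function(object, ...) {
  pos <- ring_layout(object$nodes)
  seg <- object$edges |>
    mutate(x = pos$x[match(.data$head_label, pos$label)],
           y = pos$y[match(.data$head_label, pos$label)],
           xend = pos$x[match(.data$tail_label, pos$label)],
           yend = pos$y[match(.data$tail_label, pos$label)])
  ggplot() +
    geom_segment(data = seg,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, colour = .data$source),
                 linewidth = 0.4, alpha = 0.7) +
    geom_point(data = pos, aes(x = .data$x, y = .data$y), size = 2) +
    geom_text(data = pos, aes(x = .data$x, y = .data$y, label = .data$label),
              vjust = -1, size = 3) +
    labs(title = paste0("Neighborhood of ", object$seed,
                        " (depth ", object$depth, ")"),
         x = NULL, y = NULL, colour = "source") +
    theme_minimal()
}

#' Plot an integration log
#'
#' Shows, per integrated source, the mapping outcome of its rows (mapped vs
#' skipped) and the graph density before/after integration.
#'
#' @param graph a `knowledge_graph` with at least one [integrate_source()]
#'   call in its log.
#' @return a ggplot object.
#' @export
plot_integration <- function(graph) {
  log <- integration_report(graph)
  if (!nrow(log))
    stop_litkg("no integration has been run on this graph", "litkg_invalid_input")
  long <- log |>
    select("source", mapped = "rows_mapped",
           unmapped_key = "rows_skipped_unmapped_key",
           absent_node = "rows_skipped_absent_node",
           low_score = "rows_skipped_low_score") |>
    tidyr::pivot_longer(-"source", names_to = "outcome", values_to = "rows")
  ggplot(long, aes(x = .data$source, y = .data$rows, fill = .data$outcome)) +
    geom_col(position = position_dodge()) +
    labs(title = "External source integration", x = NULL, y = "rows",
         fill = "row outcome") +
    theme_minimal()
}
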