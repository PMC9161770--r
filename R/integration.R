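# Stage 4: add relationships from external database tables onto nodes that
# already exist in the literature graph. Matching goes source key -> CUI (via
# the mapping table) -> node (via the CUI attributes on nodes). Integration
# never creates nodes: rows whose endpoints cannot be matched are counted and
# skipped, and the node set is provably unchanged.

empty_integration_log <- function() {
  tibble(
    source = character(), rows_seen = integer(), rows_mapped = integer(),
    edges_added = integer(), rows_skipped_unmapped_key = integer(),
    rows_skipped_absent_node = integer(), rows_skipped_low_score = integer(),
    density_before = double(), density_after = double()
  )
}

# CUI -> node label index; a CUI carried by several nodes resolves to the
# lexicographically smallest label (deterministic convention, surfaced in docs)
cui_label_index <- function(graph) {
  idx <- graph$nodes |>
    select("label", "cuis") |>
    tidyr::unnest_longer("cuis", values_to = "cui")
  if (!nrow(idx)) return(tibble(cui = character(), label = character()))
  idx |>
    group_by(.data$cui) |>
    summarise(label = min(.data$label), .groups = "drop")
}

#' Map external source rows onto graph node labels
#'
#' Resolves each row's two source-native keys through the CUI map and then
#' through the CUI attributes of the graph's nodes. A CUI carried by several
#' nodes resolves to the lexicographically smallest label. Misses are
#' reported per row, never raised.
#'
#' @param rows source rows ([read_source_table()]).
#' @param cui_map a CUI map ([read_cui_map()]).
#' @param graph a `knowledge_graph`.
#' @return the rows with added columns `head_label`, `tail_label` (NA when
#'   unresolved) and `status` (`"mapped"`, `"unmapped_key"` when a key is
#'   absent from the CUI map, `"absent_node"` when the CUI matches no node).
#' @export
map_rows_to_labels <- function(rows, cui_map, graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  idx <- cui_label_index(graph)
  resolve <- function(keys) {
    cui <- cui_map$cui[match(keys, cui_map$key)]
    label <- idx$label[match(cui, idx$cui)]
    list(cui = cui, label = label)
  }
  a <- resolve(rows$key_a)
  b <- resolve(rows$key_b)
  status <- dplyr::case_when(
    is.na(a$cui) | is.na(b$cui) ~ "unmapped_key",
    is.na(a$label) | is.na(b$label) ~ "absent_node",
    TRUE ~ "mapped"
  )
  rows |>
    mutate(head_label = ifelse(status == "mapped", a$label, NA_character_),
           tail_label = ifelse(status == "mapped", b$label, NA_character_),
           status = status)
}

#' Integrate an external relationship source into the graph
#'
#' For every row whose score passes `min_score` and whose two endpoints
#' resolve to existing nodes, adds (or merges, keeping the maximum score) a
#' database edge with the row's relation type and score as weight. The node
#' set is never modified. A report row is appended to the graph's integration
#' log (see [integration_report()]) recording the mapping outcome counts and
#' the graph density before and after.
#'
#' @param graph a `knowledge_graph`.
#' @param rows source rows ([read_source_table()]).
#' @param cui_map a CUI map ([read_cui_map()]).
#' @param min_score drop rows scoring below this (e.g. 700 for a STRING-style
#'   combined score, 2 for a DGIdb-style interaction score).
#' @return the updated graph.
#' @export
integrate_source <- function(graph, rows, cui_map, min_score = 0) {
  stopifnot(inherits(graph, "knowledge_graph"))
  source_name <- if (nrow(rows)) rows$source[1L] else NA_character_
  if (!is.na(source_name) && source_name %in% graph$literature_sources)
    stop_litkg("cannot integrate a table under a literature source name",
               "litkg_invalid_input")
  density_before <- kg_density(graph)
  n_nodes_before <- nrow(graph$nodes)

  scored <- rows[rows$score >= min_score, , drop = FALSE]
  n_low <- nrow(rows) - nrow(scored)
  mapped <- map_rows_to_labels(scored, cui_map, graph)
  n_unmapped_key <- sum(mapped$status == "unmapped_key")
  n_absent_node <- sum(mapped$status == "absent_node")
  ok <- mapped[mapped$status == "mapped", , drop = FALSE]

  n_edges_before <- nrow(graph$edges)
  for (i in seq_len(nrow(ok)))
    graph <- add_edge(graph, ok$head_label[i], ok$relation[i], ok$tail_label[i],
                      ok$source[i], weight = ok$score[i])
  edges_added <- nrow(graph$edges) - n_edges_before

  stopifnot(nrow(graph$nodes) == n_nodes_before)  # integration never adds nodes
  graph$integration_log <- bind_rows(graph$integration_log, tibble(
    source = source_name,
    rows_seen = nrow(rows), rows_mapped = nrow(ok),
    edges_added = edges_added,
    rows_skipped_unmapped_key = n_unmapped_key,
    rows_skipped_absent_node = n_absent_node,
    rows_skipped_low_score = n_low,
    density_before = density_before,
    density_after = kg_density(graph)
  ))
  graph
}

#' Integration log of a knowledge graph
#'
#' One row per [integrate_source()] call: row counts by mapping outcome, the
#' number of genuinely new edges, and graph density before/after. The counts
#' satisfy `rows_seen == rows_mapped + rows_skipped_unmapped_key +
#' rows_skipped_absent_node + rows_skipped_low_score` and
#' `edges_added <= rows_mapped`.
#'
#' @param graph a `knowledge_graph`.
#' @return a tibble.
#' @export
integration_report <- function(graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  graph$integration_log
}
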