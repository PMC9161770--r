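# The exploration engine. All four searches share one filter vocabulary
# (QueryOptions) and return deterministically ordered results so repeated
# queries are reproducible byte-for-byte.

#' Query filter options
#'
#' An edge passes when its predicate is in `predicates` (if set), its source
#' is in `sources` (if set), and its weight is at least the per-source
#' threshold in `min_weight_by_source` (if one is present for its source).
#' A node passes when its semantic groups intersect `node_groups` (if set).
#' `direction` constrains traversal: `"outgoing"` follows edges head to tail,
#' `"incoming"` tail to head, `"any"` both ways.
#'
#' @param predicates optional character vector of relationship types.
#' @param sources optional character vector of evidence source names.
#' @param min_weight_by_source named numeric vector, source name -> minimum
#'   edge weight (e.g. `c(STRING = 700, CORD19 = 2)`).
#' @param node_groups optional character vector of semantic group names.
#' @param direction `"any"` (default), `"outgoing"` or `"incoming"`.
#' @return a `query_options` object.
#' @export
query_options <- function(predicates = NULL, sources = NULL,
                          min_weight_by_source = NULL, node_groups = NULL,
                          direction = c("any", "outgoing", "incoming")) {
  direction <- match.arg(direction)
  if (!is.null(min_weight_by_source)) {
    if (is.null(names(min_weight_by_source)) || any(min_weight_by_source < 0))
      stop_litkg("min_weight_by_source must be a named vector of non-negative thresholds",
                 "litkg_invalid_input")
  }
  structure(
    list(predicates = predicates, sources = sources,
         min_weight_by_source = min_weight_by_source,
         node_groups = node_groups, direction = direction),
    class = "query_options"
  )
}

# vectorized edge filter over an edge tibble
edge_passes <- function(edges, opts) {
  pass <- rep(TRUE, nrow(edges))
  if (!is.null(opts$predicates)) pass <- pass & edges$predicate %in% opts$predicates
  if (!is.null(opts$sources)) pass <- pass & edges$source %in% opts$sources
  if (!is.null(opts$min_weight_by_source)) {
    thr <- opts$min_weight_by_source[edges$source]
    pass <- pass & (is.na(thr) | edges$weight >= thr)
  }
  pass
}

# vectorized node-group filter for a vector of labels
node_passes <- function(graph, labels, opts) {
  if (is.null(opts$node_groups)) return(rep(TRUE, length(labels)))
  groups <- graph$nodes$semantic_groups[match(labels, graph$nodes$label)]
  vapply(groups, function(g) length(intersect(g, opts$node_groups)) > 0, logical(1))
}

check_node_exists <- function(graph, label) {
  if (!label %in% graph$nodes$label)
    stop_litkg(paste0("node '", label, "' does not exist in the graph"),
               "litkg_missing_node")
}

#' Direct search: evidence for a known entity pair
#'
#' Returns every passing edge between the two labels under the direction rule
#' (`"outgoing"`: head to tail only; `"incoming"`: tail to head; `"any"`:
#' both), each paired with its supporting evidence, ordered by source,
#' predicate, then edge ID.
#'
#' @param graph a `knowledge_graph`.
#' @param head_label,tail_label existing node labels.
#' @param options a [query_options()] object.
#' @return a tibble of edges with an `evidence` list column of
#'   [supporting_evidence()] tables.
#' @export
direct_search <- function(graph, head_label, tail_label,
                          options = query_options()) {
  stopifnot(inherits(graph, "knowledge_graph"))
  check_node_exists(graph, head_label)
  check_node_exists(graph, tail_label)
  e <- graph$edges
  forward <- e$head_label == head_label & e$tail_label == tail_label
  backward <- e$head_label == tail_label & e$tail_label == head_label
  cand <- switch(options$direction,
                 outgoing = forward, incoming = backward,
                 any = forward | backward)
  hits <- e[cand & edge_passes(e, options), , drop = FALSE]
  hits <- hits[order(hits$source, hits$predicate, hits$edge_id, method = "radix"), ,
               drop = FALSE]
  hits$evidence <- lapply(hits$edge_id, supporting_evidence, graph = graph)
  hits
}

fuzzy_tier <- function(strings, q) {
  s <- tolower(strings)
  if (any(s == q)) return(1L)
  if (any(startsWith(s, q))) return(2L)
  if (any(stringr::str_detect(s, stringr::fixed(q)))) return(3L)
  tokens <- unlist(strsplit(s, "[^a-z0-9]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) && any(utils::adist(q, tokens) <= 2L)) return(4L)
  NA_integer_
}

#' Fuzzy entity search over labels and synonyms
#'
#' Non-fuzzy mode returns labels whose label or any synonym matches the query
#' exactly (case-insensitively). Fuzzy mode ranks candidates by match tier —
#' exact, prefix, substring, then any label/synonym token within edit
#' distance 2 — breaking ties by label length and then lexicographically.
#'
#' @param graph a `knowledge_graph`.
#' @param query_text a non-empty search string.
#' @param fuzzy use the tiered fuzzy matcher (default `TRUE`).
#' @param limit maximum number of results.
#' @return a tibble with columns `label` and `tier` (1 for exact matches),
#'   best matches first.
#' @export
fuzzy_search <- function(graph, query_text, fuzzy = TRUE, limit = 10L) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (length(query_text) != 1L || is.na(query_text) || !nzchar(query_text))
    stop_litkg("query text must be a non-empty string", "litkg_invalid_input")
  q <- tolower(query_text)
  strings <- Map(c, graph$nodes$label, graph$nodes$synonyms)
  if (fuzzy) {
    tier <- vapply(strings, fuzzy_tier, integer(1), q = q)
  } else {
    tier <- ifelse(vapply(strings, function(s) any(tolower(s) == q), logical(1)),
                   1L, NA_integer_)
  }
  out <- tibble(label = graph$nodes$label, tier = unname(tier)) |>
    filter(!is.na(.data$tier))
  out <- out[order(out$tier, nchar(out$label), out$label, method = "radix"), ,
             drop = FALSE]
  utils::head(out, limit)
}

#' Neighborhood search around a seed node
#'
#' Breadth-first expansion from the seed over passing edges and passing
#' nodes, to at most `depth` (0, 1 or 2) hops. The seed itself is exempt from
#' node-group filters. Each layer can override the base options (e.g. a
#' database-score threshold for first-layer gene-gene edges, a supporting-text
#' threshold for second-layer literature edges) via `layer_options`. The
#' result contains every visited node and every edge that passes its layer's
#' filters, connects two visited nodes, and is traversable (under the
#' direction rule) from an endpoint visited at the previous layer.
#'
#' @param graph a `knowledge_graph`.
#' @param seed_label an existing node label.
#' @param depth 0, 1 or 2.
#' @param options base [query_options()].
#' @param layer_options optional list: `layer_options[[d]]` replaces `options`
#'   for layer `d` (edges traversed at hop `d`).
#' @return a `kg_subgraph`: list with `seed`, a `nodes` tibble (label, depth,
#'   semantic groups) and an `edges` tibble.
#' @export
neighborhood <- function(graph, seed_label, depth, options = query_options(),
                         layer_options = NULL) {
  stopifnot(inherits(graph, "knowledge_graph"))
  check_node_exists(graph, seed_label)
  if (!is.numeric(depth) || length(depth) != 1L || !depth %in% 0:2)
    stop_litkg("depth must be 0, 1 or 2", "litkg_invalid_input")
  depth <- as.integer(depth)
  e <- graph$edges
  opts_for <- function(d) {
    o <- if (!is.null(layer_options) && length(layer_options) >= d &&
             !is.null(layer_options[[d]])) layer_options[[d]] else options
    stopifnot(inherits(o, "query_options"))
    o
  }
  visit_depth <- stats::setNames(0L, seed_label)
  for (d in seq_len(depth)) {
    opts_d <- opts_for(d)
    pass <- edge_passes(e, opts_d)
    frontier <- names(visit_depth)[visit_depth == d - 1L]
    from_head <- opts_d$direction %in% c("any", "outgoing")
    from_tail <- opts_d$direction %in% c("any", "incoming")
    targets <- character()
    if (from_head)
      targets <- c(targets, e$tail_label[pass & e$head_label %in% frontier])
    if (from_tail)
      targets <- c(targets, e$head_label[pass & e$tail_label %in% frontier])
    targets <- setdiff(unique(targets), names(visit_depth))
    targets <- targets[node_passes(graph, targets, opts_d)]
    if (length(targets))
      visit_depth <- c(visit_depth,
                       stats::setNames(rep(d, length(targets)), targets))
  }
  visited <- names(visit_depth)
  keep <- rep(FALSE, nrow(e))
  for (d in seq_len(depth)) {
    opts_d <- opts_for(d)
    pass <- edge_passes(e, opts_d)
    prev <- names(visit_depth)[visit_depth == d - 1L]
    if (opts_d$direction %in% c("any", "outgoing"))
      keep <- keep | (pass & e$head_label %in% prev & e$tail_label %in% visited)
    if (opts_d$direction %in% c("any", "incoming"))
      keep <- keep | (pass & e$tail_label %in% prev & e$head_label %in% visited)
  }
  edges <- e[keep, , drop = FALSE]
  edges <- edges[order(edges$edge_id, method = "radix"), , drop = FALSE]
  nodes <- tibble(label = visited, depth = unname(visit_depth)) |>
    mutate(semantic_groups =
             graph$nodes$semantic_groups[match(.data$label, graph$nodes$label)]) |>
    arrange(.data$depth, .data$label)
  structure(list(seed = seed_label, depth = depth, nodes = nodes, edges = edges),
            class = "kg_subgraph")
}

#' @export
print.kg_subgraph <- function(x, ...) {
  cat("<kg_subgraph> seed:", x$seed, " depth:", x$depth,
      " nodes:", nrow(x$nodes), " edges:", nrow(x$edges), "\n")
  invisible(x)
}

#' Bounded-length simple-path search between two entities
#'
#' Enumerates all simple paths (no repeated nodes) of edge-length
#' `min_len`..`max_len` whose every hop uses a passing edge (traversed under
#' the direction rule) and whose interior nodes pass `intermediate_groups`.
#' With `exclude_direct`, length-1 paths are removed, surfacing only mediated
#' routes. Paths are ordered by length, then lexicographically by their node
#' label sequence, then by edge IDs; parallel passing edges between the same
#' consecutive nodes yield distinct paths.
#'
#' @param graph a `knowledge_graph`.
#' @param from_label,to_label existing node labels.
#' @param min_len,max_len path length bounds in edges; `1 <= min_len <=
#'   max_len <= 4`.
#' @param exclude_direct drop single-edge paths.
#' @param intermediate_groups optional semantic groups that every interior
#'   node must intersect (e.g. restrict mediators to genes).
#' @param options a [query_options()] object.
#' @return a tibble with list columns `node_labels` and `edge_ids` and an
#'   integer `length` column, one row per path.
#' @export
find_paths <- function(graph, from_label, to_label, min_len = 1L, max_len = 3L,
                       exclude_direct = FALSE, intermediate_groups = NULL,
                       options = query_options()) {
  stopifnot(inherits(graph, "knowledge_graph"))
  check_node_exists(graph, from_label)
  check_node_exists(graph, to_label)
  if (min_len < 1L || max_len < min_len || max_len > 4L)
    stop_litkg("path length bounds must satisfy 1 <= min_len <= max_len <= 4",
               "litkg_invalid_input")
  e <- graph$edges[edge_passes(graph$edges, options), , drop = FALSE]
  hops <- switch(options$direction,
    outgoing = tibble(u = e$head_label, v = e$tail_label, edge_id = e$edge_id),
    incoming = tibble(u = e$tail_label, v = e$head_label, edge_id = e$edge_id),
    any = bind_rows(
      tibble(u = e$head_label, v = e$tail_label, edge_id = e$edge_id),
      tibble(u = e$tail_label, v = e$head_label, edge_id = e$edge_id))
  )
  adj <- split(hops[c("v", "edge_id")], hops$u)
  interior_ok <- function(labels) node_passes(
    graph, labels, list(node_groups = intermediate_groups))

  results_nodes <- list()
  results_edges <- list()
  walk <- function(node_seq, edge_seq) {
    here <- node_seq[length(node_seq)]
    len <- length(edge_seq)
    if (len >= max_len) return()
    nxt <- adj[[here]]
    if (is.null(nxt)) return()
    for (i in seq_len(nrow(nxt))) {
      v <- nxt$v[i]
      if (v %in% node_seq) next
      if (v == to_label) {
        if (len + 1L >= min_len) {
          results_nodes[[length(results_nodes) + 1L]] <<- c(node_seq, v)
          results_edges[[length(results_edges) + 1L]] <<- c(edge_seq, nxt$edge_id[i])
        }
      } else {
        if (!interior_ok(v)) next
        walk(c(node_seq, v), c(edge_seq, nxt$edge_id[i]))
      }
    }
  }
  if (from_label != to_label) walk(from_label, character())

  out <- tibble(node_labels = results_nodes, edge_ids = results_edges,
                length = lengths(results_edges))
  if (exclude_direct) out <- filter(out, .data$length > 1L)
  if (nrow(out)) {
    node_key <- vapply(out$node_labels, paste, character(1), collapse = "\r")
    edge_key <- vapply(out$edge_ids, paste, character(1), collapse = "\r")
    out <- out[order(out$length, node_key, edge_key, method = "radix"), ,
               drop = FALSE]
  }
  out
}

#' Path search over all pairs of a seed set
#'
#' Runs [find_paths()] for every unordered pair of the given labels —
#' convenient for questions like "which diseases share at least two of these
#' phenotypes", answered by inspecting the mediators common to several pairs.
#'
#' @param graph a `knowledge_graph`.
#' @param labels two or more existing node labels.
#' @param ... passed on to [find_paths()].
#' @return a tibble of paths with `from` and `to` columns prepended; pairs are
#'   taken in sorted label order.
#' @export
pairwise_paths <- function(graph, labels, ...) {
  labels <- sort(unique(labels), method = "radix")
  if (length(labels) < 2L)
    stop_litkg("pairwise_paths needs at least two distinct labels",
               "litkg_invalid_input")
  pairs <- utils::combn(labels, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    res <- find_paths(graph, pairs[1L, i], pairs[2L, i], ...)
    if (!nrow(res)) return(res)
    mutate(res, from = pairs[1L, i], to = pairs[2L, i], .before = 1L)
  })
}
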