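# Shared fixtures and independent oracles. The oracles deliberately use
# different machinery from the implementation (plain scalar loops, igraph
# enumeration, base-R table comprehensions) so agreement is evidence, not
# tautology.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Reference toy graph: a drug A, genes B and C, disorders D and E, with
# literature and database edges of known weights.
make_g0 <- function() {
  g <- kg_new(literature_sources = "CORD19")
  g <- upsert_node(g, "A", semantic_types = "phsu")
  g <- upsert_node(g, "B", semantic_types = "gngm")
  g <- upsert_node(g, "C", semantic_types = "gngm")
  g <- upsert_node(g, "D", semantic_types = "dsyn")
  g <- upsert_node(g, "E", semantic_types = "dsyn")
  g <- add_document(g, "DOC1", title = "First synthetic report",
                    authors = c("Garcia A"), journal = "Synthetic Lancet",
                    publish_date = "2020-05")
  g <- add_document(g, "DOC2", title = "Second synthetic report",
                    authors = c("Chen B", "Rossi E"),
                    journal = "Fixture Reports", publish_date = "2020-07-01")
  sentences <- c(
    "A treats B in early trials.", "A treats B in a cohort.",
    "A treats B convincingly.", "A causes D in rare cases.",
    "D treats E according to one report.", "D treats E in mice.")
  docs <- c("DOC1", "DOC1", "DOC2", "DOC2", "DOC1", "DOC2")
  for (i in seq_along(sentences)) g <- add_text(g, sentences[i], docs[i])
  g <- add_edge(g, "A", "TREATS", "B", "CORD19",
                supporting_text_ids = c("T1", "T2", "T3"))
  g <- add_edge(g, "B", "INTERACTS_WITH", "C", "STRING", weight = 900)
  g <- add_edge(g, "C", "INHIBITS", "D", "DGIDB", weight = 2)
  g <- add_edge(g, "A", "CAUSES", "D", "CORD19", supporting_text_ids = "T4")
  g <- add_edge(g, "D", "TREATS", "E", "CORD19",
                supporting_text_ids = c("T5", "T6"))
  g
}

# minimal hand-made instance table for filtration tests
make_instances <- function(head, predicate, tail, head_score = 1000L,
                           tail_score = 1000L, n = 1L, document_id = "DOC1") {
  purrr::map_dfr(seq_len(n), function(i) tibble::tibble(
    document_id = document_id, sentence_id = paste0("S", i),
    sentence = paste(head, "rel", tail, i, "."),
    head_surface = head, head_cui = "C0000001", head_name = head,
    head_types = list("gngm"), head_score = head_score,
    head_start = 0L, head_end = nchar(head),
    predicate = predicate,
    tail_surface = tail, tail_cui = "C0000002", tail_name = tail,
    tail_types = list("dsyn"), tail_score = tail_score,
    tail_start = nchar(head) + 5L, tail_end = nchar(head) + 5L + nchar(tail)
  ))
}

# --- independent filtration oracle: direct set comprehension ---------------
oracle_filter <- function(instances, min_entity_score, min_triple_count) {
  ok <- instances$head_score >= min_entity_score &
        instances$tail_score >= min_entity_score
  surv <- instances[ok, , drop = FALSE]
  key <- paste(surv$head_name, surv$predicate, surv$tail_name, sep = "\r")
  counts <- table(key)
  surv[counts[key] >= min_triple_count, , drop = FALSE]
}

# --- independent integration oracle: brute-force join ----------------------
oracle_edges_added <- function(graph, rows, cui_map, min_score = 0) {
  cui_of <- function(key) {
    hit <- cui_map$cui[cui_map$key == key]
    if (length(hit)) hit[1] else NA_character_
  }
  label_of <- function(cui) {
    labs <- character()
    for (i in seq_len(nrow(graph$nodes)))
      if (cui %in% graph$nodes$cuis[[i]]) labs <- c(labs, graph$nodes$label[i])
    if (length(labs)) min(labs) else NA_character_
  }
  existing <- paste(graph$edges$head_label, graph$edges$predicate,
                    graph$edges$tail_label, graph$edges$source, sep = "\r")
  new_keys <- character()
  for (i in seq_len(nrow(rows))) {
    if (rows$score[i] < min_score) next
    ca <- cui_of(rows$key_a[i]); cb <- cui_of(rows$key_b[i])
    if (is.na(ca) || is.na(cb)) next
    la <- label_of(ca); lb <- label_of(cb)
    if (is.na(la) || is.na(lb)) next
    k <- paste(la, rows$relation[i], lb, rows$source[i], sep = "\r")
    if (!k %in% existing) new_keys <- c(new_keys, k)
  }
  length(unique(new_keys))
}

# --- independent query oracles ---------------------------------------------
oracle_edge_pass <- function(e, o) {
  (is.null(o$predicates) || e$predicate %in% o$predicates) &&
  (is.null(o$sources) || e$source %in% o$sources) &&
  (is.null(o$min_weight_by_source) ||
     !e$source %in% names(o$min_weight_by_source) ||
     e$weight >= o$min_weight_by_source[[e$source]])
}

oracle_node_pass <- function(graph, label, groups) {
  if (is.null(groups)) return(TRUE)
  gs <- graph$nodes$semantic_groups[[match(label, graph$nodes$label)]]
  length(intersect(gs, groups)) > 0
}

# traversals (u -> v) an edge offers under a direction rule
oracle_traversals <- function(e, direction) {
  out <- list()
  if (direction %in% c("any", "outgoing"))
    out <- c(out, list(c(e$head_label, e$tail_label)))
  if (direction %in% c("any", "incoming"))
    out <- c(out, list(c(e$tail_label, e$head_label)))
  out
}

oracle_neighborhood <- function(graph, seed, depth, options = query_options(),
                                layer_options = NULL) {
  opts_for <- function(d) {
    if (!is.null(layer_options) && length(layer_options) >= d &&
        !is.null(layer_options[[d]])) layer_options[[d]] else options
  }
  vd <- stats::setNames(0L, seed)
  for (d in seq_len(depth)) {
    o <- opts_for(d)
    found <- character()
    for (i in seq_len(nrow(graph$edges))) {
      e <- as.list(graph$edges[i, ])
      if (!oracle_edge_pass(e, o)) next
      for (tr in oracle_traversals(e, o$direction)) {
        u <- tr[1]; v <- tr[2]
        if (u %in% names(vd) && vd[[u]] == d - 1L && !v %in% names(vd) &&
            oracle_node_pass(graph, v, o$node_groups))
          found <- union(found, v)
      }
    }
    if (length(found))
      vd <- c(vd, stats::setNames(rep(d, length(found)), found))
  }
  kept <- character()
  for (i in seq_len(nrow(graph$edges))) {
    e <- as.list(graph$edges[i, ])
    for (d in seq_len(depth)) {
      o <- opts_for(d)
      if (!oracle_edge_pass(e, o)) next
      for (tr in oracle_traversals(e, o$direction)) {
        u <- tr[1]; v <- tr[2]
        if (u %in% names(vd) && vd[[u]] == d - 1L && v %in% names(vd))
          kept <- union(kept, e$edge_id)
      }
    }
  }
  list(nodes = sort(names(vd)), edge_ids = sort(kept))
}

# exhaustive simple-path enumeration through igraph vertex paths, expanding
# parallel edge choices and filtering post hoc
oracle_paths <- function(graph, from, to, min_len = 1, max_len = 3,
                         exclude_direct = FALSE, intermediate_groups = NULL,
                         options = query_options()) {
  pass <- vapply(seq_len(nrow(graph$edges)),
                 function(i) oracle_edge_pass(as.list(graph$edges[i, ]), options),
                 logical(1))
  e <- graph$edges[pass, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    data.frame(from = e$head_label, to = e$tail_label,
               edge_id = e$edge_id, stringsAsFactors = FALSE),
    directed = TRUE, vertices = graph$nodes$label)
  mode <- switch(options$direction, outgoing = "out", incoming = "in", any = "all")
  vpaths <- igraph::all_simple_paths(ig, from, to, mode = mode, cutoff = max_len)
  results <- character()
  for (vp in vpaths) {
    labs <- names(vp)
    len <- length(labs) - 1L
    if (len < min_len || len > max_len) next
    if (exclude_direct && len == 1L) next
    interior <- labs[-c(1L, length(labs))]
    if (length(interior) &&
        !all(vapply(interior, oracle_node_pass, logical(1),
                    graph = graph, groups = intermediate_groups))) next
    hop_choices <- lapply(seq_len(len), function(k) {
      u <- labs[k]; v <- labs[k + 1L]
      fwd <- e$edge_id[e$head_label == u & e$tail_label == v]
      bwd <- e$edge_id[e$head_label == v & e$tail_label == u]
      switch(options$direction, outgoing = fwd, incoming = bwd,
             any = c(fwd, bwd))
    })
    if (any(lengths(hop_choices) == 0L)) next
    combos <- expand.grid(hop_choices, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos)))
      results <- c(results, paste(paste(labs, collapse = ">"),
                                  paste(unlist(combos[r, ]), collapse = ","),
                                  sep = "|"))
  }
  sort(unique(results))
}

path_signatures <- function(paths_tbl) {
  if (!nrow(paths_tbl)) return(character())
  sort(paste(
    vapply(paths_tbl$node_labels, paste, character(1), collapse = ">"),
    vapply(paths_tbl$edge_ids, paste, character(1), collapse = ","),
    sep = "|"))
}

# random graphs for oracle-equivalence properties
random_graph <- function(seed, n_nodes = 12, n_edges = 30) {
  set.seed(seed)
  g <- kg_new(literature_sources = character())
  types <- names(default_type_groups())
  labels <- sprintf("N%02d", seq_len(n_nodes))
  for (lab in labels)
    g <- upsert_node(g, lab, semantic_types = sample(types, sample(1:2, 1)))
  sources <- c("CORD19", "STRING", "DGIDB", "DISGENET")
  predicates <- c("TREATS", "CAUSES", "INTERACTS_WITH", "AFFECTS")
  tries <- 0
  while (nrow(g$edges) < n_edges && tries < n_edges * 10) {
    tries <- tries + 1
    ht <- sample(labels, 2)
    g <- add_edge(g, ht[1], sample(predicates, 1), ht[2], sample(sources, 1),
                  weight = sample(c(1:10, 100 * 1:10), 1))
  }
  g
}

random_options <- function(seed) {
  set.seed(seed)
  pick <- function(x, p = 0.5) if (stats::runif(1) < p) x else NULL
  query_options(
    predicates = pick(sample(c("TREATS", "CAUSES", "INTERACTS_WITH", "AFFECTS"),
                             sample(2:4, 1))),
    sources = pick(sample(c("CORD19", "STRING", "DGIDB", "DISGENET"),
                          sample(2:4, 1))),
    min_weight_by_source = pick(c(STRING = sample(c(2, 5, 300, 700), 1),
                                  CORD19 = sample(1:3, 1)), 0.5),
    node_groups = pick(sample(unique(unname(default_type_groups())), 3), 0.4),
    direction = sample(c("any", "outgoing", "incoming"), 1)
  )
}

# one small corpus + matching source tables, parsed and run through the
# pipeline stages in memory; used by several suites
build_fixture_graph <- function(seed, dir = tempfile("fixture"), n_planted = 8) {
  manifest <- generate_corpus(seed, n_documents = 10, n_entities = 20,
                              n_planted_triples = n_planted,
                              noise = list(n_low_score = 6, n_singleton = 5,
                                           n_inferred = 4, n_variant_triples = 2),
                              dir = dir)
  instances <- read_predications(manifest$files$predications) |>
    strip_inferred() |>
    normalize_instances(read_dictionary(manifest$files$dictionary)) |>
    filter_instances()
  built <- build_graph(instances)
  graph <- register_texts(built$graph, built$text_drafts,
                          read_documents(manifest$files$documents))
  graph <- attach_impact_factors(graph, read_impact_factors(manifest$files$jif))
  list(graph = graph, manifest = manifest, instances = instances,
       drafts = built$text_drafts)
}
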