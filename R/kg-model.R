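#' @importFrom rlang abort %||% .data
#' @importFrom dplyr filter mutate select arrange bind_rows distinct group_by
#'   summarise ungroup left_join anti_join semi_join n row_number across
#' @importFrom tibble tibble as_tibble
NULL

# canonical set representation: sorted unique non-empty strings
as_set <- function(x) {
  x <- as.character(x)
  sort(unique(x[!is.na(x) & nzchar(x)]), method = "radix")
}

stop_litkg <- function(message, class, ...) {
  abort(message, class = c(class, "litkg_error"), ...)
}

empty_nodes <- function() {
  tibble(
    label = character(), preferred_name = character(),
    cuis = list(), semantic_types = list(), semantic_groups = list(),
    synonyms = list()
  )
}

empty_edges <- function() {
  tibble(
    edge_id = character(), head_label = character(), tail_label = character(),
    predicate = character(), source = character(), weight = double(),
    supporting_text_ids = list()
  )
}

empty_texts <- function() {
  tibble(
    text_id = character(), sentence = character(), document_id = character(),
    head_start = integer(), head_end = integer(),
    predicate_start = integer(), predicate_end = integer(),
    tail_start = integer(), tail_end = integer()
  )
}

empty_documents <- function() {
  tibble(
    document_id = character(), title = character(), authors = list(),
    journal = character(), publish_date = character(), impact_factor = double()
  )
}

#' Create an empty knowledge graph
#'
#' A knowledge graph holds three kinds of records: concept nodes (ITEMs),
#' deduplicated supporting sentences (TEXTs) and source articles (DOCUMENTs).
#' Nodes are keyed by their label string; concept identifiers (CUIs) are
#' attributes, not keys, so one node may carry several. Edges are unique per
#' (head, predicate, tail, source); parallel edges from different evidence
#' sources are kept separate so queries can filter per source.
#'
#' @param type_to_group named character vector mapping semantic-type codes
#'   (e.g. `"gngm"`) to semantic-group names (e.g.
#'   `"Genes & Molecular Sequences"`). Defaults to [default_type_groups()].
#' @param literature_sources character vector of source names whose edges carry
#'   supporting texts; for these, edge weight is defined as the number of
#'   supporting texts rather than a database score.
#' @return a `knowledge_graph` object.
#' @seealso [upsert_node()], [add_edge()], [kg_density()], [kg_validate()]
#' @export
#' @examples
#' g <- kg_new()
#' g <- upsert_node(g, "ACE2", cuis = "C1422064", semantic_types = "gngm")
#' glance(g)
kg_new <- function(type_to_group = default_type_groups(),
                   literature_sources = "CORD19") {
  stopifnot(is.character(literature_sources))
  if (length(type_to_group) && is.null(names(type_to_group)))
    stop_litkg("`type_to_group` must be a named character vector", "litkg_invalid_input")
  structure(
    list(
      nodes = empty_nodes(), edges = empty_edges(),
      texts = empty_texts(), documents = empty_documents(),
      type_to_group = type_to_group,
      literature_sources = literature_sources,
      integration_log = empty_integration_log(),
      edge_counter = 0L, text_counter = 0L
    ),
    class = "knowledge_graph"
  )
}

#' Default semantic type-to-group map
#'
#' A small map from UMLS-style semantic-type codes to the coarse semantic
#' groups used for node filtering in queries. Users with richer type systems
#' supply their own map to [kg_new()].
#'
#' @return named character vector (type code -> group name).
#' @export
default_type_groups <- function() {
  c(
    gngm = "Genes & Molecular Sequences",
    aapp = "Chemicals & Drugs",
    phsu = "Chemicals & Drugs",
    orch = "Chemicals & Drugs",
    dsyn = "Disorders",
    sosy = "Disorders",
    patf = "Disorders",
    virs = "Living Beings",
    humn = "Living Beings",
    ortf = "Anatomy",
    celc = "Anatomy",
    biof = "Physiology",
    moft = "Physiology"
  )
}

groups_for_types <- function(types, type_to_group) {
  as_set(unname(type_to_group[intersect(types, names(type_to_group))]))
}

#' Insert or merge a concept node
#'
#' Nodes are uniquely identified by their label. Inserting a label that already
#' exists merges by set union of CUIs, semantic types and synonyms; the
#' preferred name of the first insertion is kept. Semantic groups are always
#' recomputed from the (merged) semantic types via the graph's type-to-group
#' map. The operation is idempotent.
#'
#' @param graph a `knowledge_graph`.
#' @param label node label (primary key); must be a non-empty string.
#' @param preferred_name display name; defaults to the label.
#' @param cuis,semantic_types,synonyms character vectors (treated as sets).
#' @return the updated graph.
#' @export
upsert_node <- function(graph, label, preferred_name = label,
                        cuis = character(), semantic_types = character(),
                        synonyms = character()) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (length(label) != 1L || is.na(label) || !nzchar(label))
    stop_litkg("node label must be a single non-empty string", "litkg_invalid_input")
  upsert_nodes_tbl(graph, tibble(
    label = label, preferred_name = preferred_name,
    cuis = list(as_set(cuis)), semantic_types = list(as_set(semantic_types)),
    synonyms = list(as_set(synonyms))
  ))
}

# bulk upsert; `nodes` has columns label, preferred_name, cuis, semantic_types,
# synonyms (list columns already set-canonical). Rows may repeat a label.
upsert_nodes_tbl <- function(graph, nodes) {
  if (!nrow(nodes)) return(graph)
  if (any(is.na(nodes$label) | !nzchar(nodes$label)))
    stop_litkg("node label must be a single non-empty string", "litkg_invalid_input")
  combined <- bind_rows(
    graph$nodes |> select("label", "preferred_name", "cuis", "semantic_types", "synonyms"),
    nodes |> select("label", "preferred_name", "cuis", "semantic_types", "synonyms")
  )
  merged <- combined |>
    group_by(.data$label) |>
    summarise(
      preferred_name = .data$preferred_name[1L],   # first insertion wins
      cuis = list(as_set(unlist(.data$cuis))),
      semantic_types = list(as_set(unlist(.data$semantic_types))),
      synonyms = list(as_set(unlist(.data$synonyms))),
      .groups = "drop"
    )
  # preserve original insertion order, appending genuinely new labels
  order_ref <- c(graph$nodes$label, setdiff(unique(nodes$label), graph$nodes$label))
  merged <- merged[match(order_ref, merged$label), , drop = FALSE]
  merged$semantic_groups <- lapply(merged$semantic_types, groups_for_types,
                                   type_to_group = graph$type_to_group)
  graph$nodes <- merged |>
    select("label", "preferred_name", "cuis", "semantic_types",
           "semantic_groups", "synonyms")
  graph
}

#' Add or merge a relationship edge
#'
#' Edges are unique per (head, predicate, tail, source). Adding an existing
#' combination merges: supporting-text IDs are unioned and, for literature
#' sources, the weight is recomputed as the number of supporting texts (the
#' graph's confidence currency for literature evidence); for database sources
#' the maximum of the two weights is kept. Both endpoints must already exist —
#' edge integration never creates nodes.
#'
#' @param graph a `knowledge_graph`.
#' @param head_label,tail_label labels of existing nodes.
#' @param predicate relationship type string (e.g. `"TREATS"`).
#' @param source evidence source name (e.g. `"CORD19"`, `"STRING"`).
#' @param weight non-negative confidence; required for non-literature sources,
#'   ignored (recomputed) for literature sources.
#' @param supporting_text_ids character vector of text IDs backing a
#'   literature edge; must be empty for non-literature sources.
#' @return the updated graph. Retrieve the edge's ID with [edge_id_of()].
#' @export
add_edge <- function(graph, head_label, predicate, tail_label, source,
                     weight = NULL, supporting_text_ids = character()) {
  stopifnot(inherits(graph, "knowledge_graph"))
  for (lab in c(head_label, tail_label)) {
    if (!lab %in% graph$nodes$label)
      stop_litkg(paste0("node '", lab, "' does not exist in the graph"),
                 "litkg_missing_node")
  }
  if (length(predicate) != 1L || is.na(predicate) || !nzchar(predicate))
    stop_litkg("predicate must be a non-empty string", "litkg_invalid_input")
  literature <- source %in% graph$literature_sources
  ids <- as.character(supporting_text_ids)
  if (!literature && length(ids))
    stop_litkg("supporting texts are only valid for literature sources",
               "litkg_invalid_input")
  if (!literature) {
    if (is.null(weight) || is.na(weight) || weight < 0)
      stop_litkg("a non-negative weight is required for database sources",
                 "litkg_invalid_input")
  }
  hit <- which(graph$edges$head_label == head_label &
               graph$edges$predicate == predicate &
               graph$edges$tail_label == tail_label &
               graph$edges$source == source)
  if (length(hit)) {
    merged_ids <- unique(c(graph$edges$supporting_text_ids[[hit]], ids))
    graph$edges$supporting_text_ids[[hit]] <- merged_ids
    graph$edges$weight[hit] <-
      if (literature) length(merged_ids)
      else max(graph$edges$weight[hit], as.numeric(weight))
  } else {
    graph$edge_counter <- graph$edge_counter + 1L
    ids <- unique(ids)
    graph$edges <- bind_rows(graph$edges, tibble(
      edge_id = paste0("E", graph$edge_counter),
      head_label = head_label, tail_label = tail_label,
      predicate = predicate, source = source,
      weight = if (literature) length(ids) else as.numeric(weight),
      supporting_text_ids = list(ids)
    ))
  }
  graph
}

#' Look up an edge ID by its identifying key
#'
#' @inheritParams add_edge
#' @return the edge ID string, or `NA` if no such edge exists.
#' @export
edge_id_of <- function(graph, head_label, predicate, tail_label, source) {
  hit <- graph$edges$edge_id[
    graph$edges$head_label == head_label & graph$edges$predicate == predicate &
    graph$edges$tail_label == tail_label & graph$edges$source == source]
  if (length(hit)) hit[1L] else NA_character_
}

#' Register a source article
#'
#' @param graph a `knowledge_graph`.
#' @param document_id corpus article ID (unique).
#' @param title,journal strings.
#' @param authors character vector of author names.
#' @param publish_date lenient ISO date (`YYYY`, `YYYY-MM` or `YYYY-MM-DD`);
#'   stored normalized.
#' @param impact_factor optional non-negative number; normally attached later
#'   by [attach_impact_factors()].
#' @return the updated graph.
#' @export
add_document <- function(graph, document_id, title = "", authors = character(),
                         journal = "", publish_date = NA_character_,
                         impact_factor = NA_real_) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (length(document_id) != 1L || is.na(document_id) || !nzchar(document_id))
    stop_litkg("document_id must be a non-empty string", "litkg_invalid_input")
  if (document_id %in% graph$documents$document_id) return(graph)
  graph$documents <- bind_rows(graph$documents, tibble(
    document_id = document_id, title = title,
    authors = list(as.character(authors)), journal = journal,
    publish_date = normalize_date(publish_date),
    impact_factor = as.numeric(impact_factor)
  ))
  graph
}

# lenient date parsing: YYYY, YYYY-M(M), YYYY-M(M)-D(D); stored zero-padded
normalize_date <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  parts <- strsplit(trimws(x), "-", fixed = TRUE)[[1L]]
  if (!length(parts) %in% 1:3 || anyNA(suppressWarnings(as.integer(parts))))
    stop_litkg(paste0("cannot parse date '", x, "'"), "litkg_invalid_input")
  n <- as.integer(parts)
  switch(length(n),
         sprintf("%04d", n[1]),
         sprintf("%04d-%02d", n[1], n[2]),
         sprintf("%04d-%02d-%02d", n[1], n[2], n[3]))
}

check_span <- function(span, sentence_len, what) {
  if (is.null(span) || all(is.na(span))) return(c(NA_integer_, NA_integer_))
  span <- as.integer(span)
  if (length(span) != 2L || span[1] < 0L || span[2] <= span[1] ||
      span[2] > sentence_len)
    stop_litkg(paste0(what, " span must be a half-open [start, end) within the sentence"),
               "litkg_invalid_input")
  span
}

#' Register a supporting sentence
#'
#' Character spans are 0-based half-open intervals into the sentence, and must
#' not overlap one another.
#'
#' @param graph a `knowledge_graph`.
#' @param sentence the verbatim supporting sentence (non-empty).
#' @param document_id article the sentence came from (must be registered).
#' @param text_id optional explicit ID; autogenerated (`T1`, `T2`, ...) if `NULL`.
#' @param head_span,predicate_span,tail_span optional `c(start, end)` integer
#'   pairs locating the triple's parts in the sentence.
#' @return the updated graph, with the new text's ID in attribute `"text_id"`.
#' @export
add_text <- function(graph, sentence, document_id, text_id = NULL,
                     head_span = NULL, predicate_span = NULL, tail_span = NULL) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (length(sentence) != 1L || is.na(sentence) || !nzchar(sentence))
    stop_litkg("sentence must be non-empty", "litkg_invalid_input")
  if (!document_id %in% graph$documents$document_id)
    stop_litkg(paste0("document '", document_id, "' is not registered"),
               "litkg_missing_document")
  len <- nchar(sentence)
  hs <- check_span(head_span, len, "head")
  ps <- check_span(predicate_span, len, "predicate")
  ts <- check_span(tail_span, len, "tail")
  spans <- list(hs, ps, ts)
  spans <- spans[!vapply(spans, function(s) anyNA(s), logical(1))]
  if (length(spans) > 1L) {
    ord <- order(vapply(spans, `[`, integer(1), 1L))
    spans <- spans[ord]
    for (i in seq_len(length(spans) - 1L))
      if (spans[[i]][2] > spans[[i + 1L]][1])
        stop_litkg("entity/predicate spans must not overlap", "litkg_invalid_input")
  }
  if (is.null(text_id)) {
    graph$text_counter <- graph$text_counter + 1L
    text_id <- paste0("T", graph$text_counter)
  } else if (text_id %in% graph$texts$text_id) {
    stop_litkg(paste0("text ID '", text_id, "' already exists"), "litkg_invalid_input")
  }
  graph$texts <- bind_rows(graph$texts, tibble(
    text_id = text_id, sentence = sentence, document_id = document_id,
    head_start = hs[1], head_end = hs[2],
    predicate_start = ps[1], predicate_end = ps[2],
    tail_start = ts[1], tail_end = ts[2]
  ))
  attr(graph, "text_id") <- text_id
  graph
}

#' Graph density over unique triples
#'
#' Density is the number of unique directed (head, predicate, tail) triples —
#' collapsed across evidence sources, so parallel multi-source edges count
#' once — divided by the number of ordered node pairs, `N * (N - 1)`. Graphs
#' with at most one node have density 0 by convention. Integrating external
#' relationship sources onto a literature graph raises this quantity; the
#' before/after ratio summarises the enrichment.
#'
#' @param graph a `knowledge_graph`.
#' @return a single non-negative number.
#' @export
#' @examples
#' kg_density(kg_new())  # 0
kg_density <- function(graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  n <- nrow(graph$nodes)
  if (n <= 1L) return(0)
  e_u <- nrow(distinct(graph$edges, .data$head_label, .data$predicate, .data$tail_label))
  e_u / (n * (n - 1))
}

#' Validate graph integrity
#'
#' Sweeps the store and aborts on the first violation: dangling edge endpoints,
#' supporting-text IDs not present in the text store, texts referencing
#' unregistered documents, duplicate (head, predicate, tail, source) edges, or
#' literature edges whose weight differs from their supporting-text count.
#'
#' @param graph a `knowledge_graph`.
#' @return the graph, invisibly, if valid.
#' @export
kg_validate <- function(graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  e <- graph$edges
  bad <- setdiff(c(e$head_label, e$tail_label), graph$nodes$label)
  if (length(bad))
    stop_litkg(paste0("edge endpoint(s) missing from node store: ",
                      paste(bad, collapse = ", ")), "litkg_integrity_error")
  if (anyDuplicated(graph$nodes$label))
    stop_litkg("duplicate node labels", "litkg_integrity_error")
  key <- paste(e$head_label, e$predicate, e$tail_label, e$source, sep = "\r")
  if (anyDuplicated(key))
    stop_litkg("duplicate (head, predicate, tail, source) edges", "litkg_integrity_error")
  tids <- unlist(e$supporting_text_ids)
  dangling <- setdiff(tids, graph$texts$text_id)
  if (length(dangling))
    stop_litkg(paste0("supporting text ID(s) missing from text store: ",
                      paste(dangling, collapse = ", ")), "litkg_integrity_error")
  lost_docs <- setdiff(graph$texts$document_id, graph$documents$document_id)
  if (length(lost_docs))
    stop_litkg(paste0("text(s) reference unregistered document(s): ",
                      paste(lost_docs, collapse = ", ")), "litkg_integrity_error")
  lit <- e$source %in% graph$literature_sources
  n_texts <- lengths(e$supporting_text_ids)
  if (any(lit & e$weight != n_texts))
    stop_litkg("literature edge weight differs from its supporting-text count",
               "litkg_integrity_error")
  if (any(!lit & n_texts > 0))
    stop_litkg("non-literature edge carries supporting texts", "litkg_integrity_error")
  if (any(e$weight < 0))
    stop_litkg("negative edge weight", "litkg_integrity_error")
  invisible(graph)
}

#' Order-insensitive graph equality
#'
#' Two graphs are equal when they hold the same nodes (with equal attribute
#' sets), the same edges keyed by (head, predicate, tail, source) with equal
#' weights and supporting-text sets, and the same texts and documents. Opaque
#' edge IDs and row order are ignored.
#'
#' @param a,b `knowledge_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
kg_equal <- function(a, b) {
  canon_nodes <- function(g) {
    g$nodes |>
      mutate(across(c("cuis", "semantic_types", "semantic_groups", "synonyms"),
                    ~ vapply(.x, function(s) paste(as_set(s), collapse = ";"),
                             character(1)))) |>
      arrange(.data$label)
  }
  canon_edges <- function(g) {
    g$edges |>
      mutate(texts = vapply(.data$supporting_text_ids,
                            function(s) paste(sort(s), collapse = ";"), character(1))) |>
      select("head_label", "predicate", "tail_label", "source", "weight", "texts") |>
      arrange(.data$head_label, .data$predicate, .data$tail_label, .data$source)
  }
  canon_texts <- function(g) arrange(g$texts, .data$text_id)
  canon_docs <- function(g) {
    g$documents |>
      mutate(authors = vapply(.data$authors, paste, character(1), collapse = ";")) |>
      arrange(.data$document_id)
  }
  isTRUE(all.equal(canon_nodes(a), canon_nodes(b))) &&
    isTRUE(all.equal(canon_edges(a), canon_edges(b))) &&
    isTRUE(all.equal(canon_texts(a), canon_texts(b))) &&
    isTRUE(all.equal(canon_docs(a), canon_docs(b)))
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("<knowledge_graph>\n")
  cat("  nodes:     ", nrow(x$nodes), "\n")
  cat("  edges:     ", nrow(x$edges), " (",
      nrow(distinct(x$edges, .data$head_label, .data$predicate, .data$tail_label)),
      " unique triples)\n", sep = "")
  cat("  texts:     ", nrow(x$texts), "\n")
  cat("  documents: ", nrow(x$documents), "\n")
  cat("  sources:   ", paste(sort(unique(x$edges$source)), collapse = ", "), "\n")
  cat("  density:   ", format(kg_density(x), digits = 4), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a knowledge graph into its edge table
#'
#' @param x a `knowledge_graph`.
#' @param ... unused.
#' @return a tibble with one row per edge: endpoints, predicate, source,
#'   weight and the number of supporting texts.
#' @method tidy knowledge_graph
#' @export
tidy.knowledge_graph <- function(x, ...) {
  x$edges |>
    mutate(n_supporting_texts = lengths(.data$supporting_text_ids)) |>
    select("edge_id", "head_label", "predicate", "tail_label", "source",
           "weight", "n_supporting_texts")
}

#' One-row summary of a knowledge graph
#'
#' @param x a `knowledge_graph`.
#' @param ... unused.
#' @return a one-row tibble: node, edge, unique-triple, text and document
#'   counts, number of evidence sources, and density.
#' @method glance knowledge_graph
#' @export
glance.knowledge_graph <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_unique_triples = nrow(distinct(x$edges, .data$head_label,
                                     .data$predicate, .data$tail_label)),
    n_texts = nrow(x$texts),
    n_documents = nrow(x$documents),
    n_sources = length(unique(x$edges$source)),
    density = kg_density(x)
  )
}
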