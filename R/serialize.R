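# Native JSON-lines serialization: one file per record kind plus a manifest
# with counts. Arrays stay arrays; absent spans / impact factors are null.

span_or_null <- function(s, e) {
  if (is.na(s)) NULL else c(as.integer(s), as.integer(e))
}

#' Write a knowledge graph in the native JSON-lines layout
#'
#' Emits `nodes.jsonl`, `edges.jsonl`, `texts.jsonl`, `documents.jsonl` (one
#' JSON object per line, field names matching the record definitions) and a
#' `manifest.json` with record counts, the type-to-group map and the
#' literature-source list.
#'
#' @param graph a `knowledge_graph`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
kg_write_jsonl <- function(graph, dir) {
  stopifnot(inherits(graph, "knowledge_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_lines_json <- function(records, file) {
    con <- file(file.path(dir, file), open = "wb")
    on.exit(close(con))
    for (rec in records)
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                  digits = NA),
                 con, useBytes = TRUE)
  }
  nodes <- purrr::pmap(graph$nodes, function(label, preferred_name, cuis,
                                             semantic_types, semantic_groups,
                                             synonyms) {
    list(label = label, preferred_name = preferred_name, cuis = cuis,
         semantic_types = semantic_types, semantic_groups = semantic_groups,
         synonyms = synonyms)
  })
  edges <- purrr::pmap(graph$edges, function(edge_id, head_label, tail_label,
                                             predicate, source, weight,
                                             supporting_text_ids) {
    list(edge_id = edge_id, head_label = head_label, tail_label = tail_label,
         predicate = predicate, source = source, weight = weight,
         supporting_text_ids = supporting_text_ids)
  })
  texts <- purrr::pmap(graph$texts, function(text_id, sentence, document_id,
                                             head_start, head_end,
                                             predicate_start, predicate_end,
                                             tail_start, tail_end) {
    list(text_id = text_id, sentence = sentence, document_id = document_id,
         head_span = span_or_null(head_start, head_end),
         predicate_span = span_or_null(predicate_start, predicate_end),
         tail_span = span_or_null(tail_start, tail_end))
  })
  docs <- purrr::pmap(graph$documents, function(document_id, title, authors,
                                                journal, publish_date,
                                                impact_factor) {
    list(document_id = document_id, title = title, authors = authors,
         journal = journal,
         publish_date = if (is.na(publish_date)) NULL else publish_date,
         impact_factor = if (is.na(impact_factor)) NULL else impact_factor)
  })
  write_lines_json(nodes, "nodes.jsonl")
  write_lines_json(edges, "edges.jsonl")
  write_lines_json(texts, "texts.jsonl")
  write_lines_json(docs, "documents.jsonl")
  manifest <- list(
    n_nodes = nrow(graph$nodes), n_edges = nrow(graph$edges),
    n_texts = nrow(graph$texts), n_documents = nrow(graph$documents),
    type_to_group = as.list(graph$type_to_group),
    literature_sources = graph$literature_sources
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a knowledge graph from the native JSON-lines layout
#'
#' @param dir directory written by [kg_write_jsonl()].
#' @return a `knowledge_graph`.
#' @export
kg_read_jsonl <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  graph <- kg_new(
    type_to_group = unlist(manifest$type_to_group) %||% character(),
    literature_sources = unlist(manifest$literature_sources) %||% character()
  )
  read_records <- function(file) {
    lines <- readLines(file.path(dir, file), encoding = "UTF-8")
    lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  }
  chr0 <- function(x) if (is.null(x)) character() else as.character(x)
  for (rec in read_records("nodes.jsonl"))
    graph <- upsert_node(graph, rec$label, rec$preferred_name,
                         cuis = chr0(rec$cuis),
                         semantic_types = chr0(rec$semantic_types),
                         synonyms = chr0(rec$synonyms))
  for (rec in read_records("documents.jsonl"))
    graph <- add_document(graph, rec$document_id, rec$title %||% "",
                          authors = chr0(rec$authors),
                          journal = rec$journal %||% "",
                          publish_date = rec$publish_date %||% NA_character_,
                          impact_factor = rec$impact_factor %||% NA_real_)
  for (rec in read_records("texts.jsonl"))
    graph <- add_text(graph, rec$sentence, rec$document_id,
                      text_id = rec$text_id,
                      head_span = rec$head_span, predicate_span = rec$predicate_span,
                      tail_span = rec$tail_span)
  for (rec in read_records("edges.jsonl")) {
    lit <- rec$source %in% graph$literature_sources
    graph <- add_edge(graph, rec$head_label, rec$predicate, rec$tail_label,
                      rec$source,
                      weight = if (lit) NULL else rec$weight,
                      supporting_text_ids = chr0(rec$supporting_text_ids))
  }
  graph$text_counter <- max(graph$text_counter,
                            suppressWarnings(max(0L, as.integer(
                              sub("^T", "", grep("^T[0-9]+$", graph$texts$text_id,
                                                 value = TRUE))))))
  kg_validate(graph)
  graph
}
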