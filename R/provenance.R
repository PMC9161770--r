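# Stage 3: deduplicate supporting sentences, register article metadata, and
# serve evidence lookups. Supporting texts are stored once per unique
# (document, sentence) pair — the same sentence string appearing in two
# different abstracts is two records — and edges re-point at the merged IDs.

#' Register supporting texts and their source articles
#'
#' Deduplicates text drafts by exact (document ID, sentence string) identity,
#' rewrites every edge's supporting-text IDs onto the merged records
#' (collapsing duplicates and recomputing literature edge weights as the new
#' supporting-text counts), and registers each referenced article once from
#' the metadata table.
#'
#' @param graph a `knowledge_graph` as built by [build_graph()].
#' @param text_drafts draft tibble from [build_graph()].
#' @param documents article metadata tibble ([read_documents()]).
#' @return the updated graph.
#' @export
register_texts <- function(graph, text_drafts, documents) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (!nrow(text_drafts)) return(graph)
  missing_docs <- setdiff(text_drafts$document_id, documents$document_id)
  if (length(missing_docs))
    stop_litkg(paste0("text draft(s) reference unknown document(s): ",
                      paste(unique(missing_docs), collapse = ", ")),
               "litkg_missing_document")

  key <- paste(text_drafts$document_id, text_drafts$sentence, sep = "\r")
  first_seen <- match(key, key)            # index of each draft's canonical row
  canon_rows <- sort(unique(first_seen))
  merged_ids <- paste0("T", graph$text_counter + seq_along(canon_rows))
  id_map <- stats::setNames(merged_ids[match(first_seen, canon_rows)],
                            text_drafts$text_id)

  merged <- text_drafts[canon_rows, , drop = FALSE]
  merged$text_id <- merged_ids
  graph$texts <- bind_rows(graph$texts, merged)
  graph$text_counter <- graph$text_counter + length(canon_rows)

  lit <- graph$edges$source %in% graph$literature_sources
  graph$edges$supporting_text_ids <- lapply(
    graph$edges$supporting_text_ids,
    function(ids) {
      known <- ids %in% names(id_map)
      ids[known] <- unname(id_map[ids[known]])
      unique(ids)
    })
  graph$edges$weight[lit] <- lengths(graph$edges$supporting_text_ids[lit])

  used_docs <- unique(text_drafts$document_id)
  docs <- documents[documents$document_id %in% used_docs, , drop = FALSE]
  for (i in seq_len(nrow(docs)))
    graph <- add_document(graph, docs$document_id[i], docs$title[i],
                          authors = docs$authors[[i]], journal = docs$journal[i],
                          publish_date = docs$publish_date[i])
  graph
}

normalize_journal <- function(x) stringr::str_squish(tolower(x))

#' Attach journal impact factors to registered articles
#'
#' Matches on journal name after case folding and whitespace normalization;
#' articles whose journal is absent from the table keep their impact factor
#' unset. The number of matched articles is recorded in the `"n_attached"`
#' attribute of the returned graph.
#'
#' @param graph a `knowledge_graph` with registered documents.
#' @param jif tibble with columns `journal`, `impact_factor`
#'   ([read_impact_factors()]).
#' @return the updated graph (attribute `"n_attached"` holds the match count).
#' @export
attach_impact_factors <- function(graph, jif) {
  stopifnot(inherits(graph, "knowledge_graph"))
  n_attached <- 0L
  if (nrow(jif) && nrow(graph$documents)) {
    key <- normalize_journal(jif$journal)
    idx <- match(normalize_journal(graph$documents$journal), key)
    hit <- !is.na(idx)
    graph$documents$impact_factor[hit] <- jif$impact_factor[idx[hit]]
    n_attached <- sum(hit)
  }
  attr(graph, "n_attached") <- n_attached
  graph
}

#' Retrieve the supporting evidence behind an edge
#'
#' Resolves a literature edge's supporting-text IDs, in stored order, to their
#' sentences and article metadata. Database-derived edges have no supporting
#' texts and yield an empty table.
#'
#' @param graph a `knowledge_graph`.
#' @param edge_id an existing edge ID (see [edge_id_of()], [tidy()]).
#' @return a tibble with one row per supporting text: `text_id`, `sentence`,
#'   `document_id`, `title`, `authors` (list), `journal`, `publish_date`,
#'   `impact_factor`.
#' @export
supporting_evidence <- function(graph, edge_id) {
  stopifnot(inherits(graph, "knowledge_graph"))
  hit <- match(edge_id, graph$edges$edge_id)
  if (is.na(hit))
    stop_litkg(paste0("no edge with ID '", edge_id, "'"), "litkg_missing_edge")
  ids <- graph$edges$supporting_text_ids[[hit]]
  empty <- tibble(text_id = character(), sentence = character(),
                  document_id = character(), title = character(),
                  authors = list(), journal = character(),
                  publish_date = character(), impact_factor = double())
  if (!length(ids)) return(empty)
  tpos <- match(ids, graph$texts$text_id)
  if (anyNA(tpos))
    stop_litkg(paste0("edge '", edge_id, "' references unknown text ID(s): ",
                      paste(ids[is.na(tpos)], collapse = ", ")),
               "litkg_integrity_error")
  texts <- graph$texts[tpos, c("text_id", "sentence", "document_id")]
  dpos <- match(texts$document_id, graph$documents$document_id)
  if (anyNA(dpos))
    stop_litkg("supporting text references an unregistered document",
               "litkg_integrity_error")
  docs <- graph$documents[dpos, c("title", "authors", "journal",
                                  "publish_date", "impact_factor")]
  bind_rows(empty, dplyr::bind_cols(texts, docs))
}
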