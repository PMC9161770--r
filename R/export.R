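# Stage 5: serialize the graph into the property-graph bulk-import CSV
# dialect (one nodes file per record kind, one relationships file per edge
# kind). RFC 4180 quoting; array-valued fields are ';'-delimited, so ';' is
# forbidden inside array elements; rows are sorted by ID so identical graphs
# export byte-identically.

join_array <- function(xs, what) {
  vapply(xs, function(x) {
    if (any(grepl(";", x, fixed = TRUE)))
      stop_litkg(paste0(what, " values must not contain ';' (array delimiter)"),
                 "litkg_invalid_input")
    paste(x, collapse = ";")
  }, character(1))
}

split_array <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1L]]
  })
}

span_str <- function(s, e) ifelse(is.na(s), "", paste0(s, "-", e))

span_unstr <- function(x) {
  out <- matrix(NA_integer_, nrow = length(x), ncol = 2L)
  has <- !is.na(x) & nzchar(x)
  if (any(has)) {
    parts <- strsplit(x[has], "-", fixed = TRUE)
    out[has, 1L] <- as.integer(vapply(parts, `[`, character(1), 1L))
    out[has, 2L] <- as.integer(vapply(parts, `[`, character(1), 2L))
  }
  out
}

BULK_HEADERS <- list(
  nodes = c("label:ID", "preferredName", "cuis:string[]",
            "semanticTypes:string[]", "semanticGroups:string[]",
            "synonyms:string[]", ":LABEL"),
  texts = c("text_id:ID", "sentence", "headSpan", "predicateSpan", "tailSpan",
            ":LABEL"),
  documents = c("document_id:ID", "title", "authors:string[]", "journal",
                "publishDate", "impactFactor:float", ":LABEL"),
  edges = c(":START_ID", ":END_ID", ":TYPE", "source", "weight:float",
            "supportingTextIds:string[]"),
  in_document = c(":START_ID", ":END_ID", ":TYPE")
)

#' Write a graph in the bulk-import CSV dialect
#'
#' Emits `nodes.csv`, `texts.csv` and `documents.csv` (node files for the
#' ITEM, TEXT and DOCUMENT record kinds) plus `edges.csv` (ITEM-to-ITEM
#' relationships, typed by predicate) and `in_document.csv` (TEXT-to-DOCUMENT
#' links), in the header dialect of graph-database bulk importers:
#' `field:ID`, `:START_ID`/`:END_ID`/`:TYPE`/`:LABEL` role columns, and
#' `;`-delimited `string[]` array fields. Node IDs are the node labels
#' themselves. The graph is validated first; nothing is written for an
#' invalid graph. Rows are sorted by ID, so exports are byte-identical for
#' equal graphs.
#'
#' @param graph a `knowledge_graph`.
#' @param out_dir output directory (created if needed).
#' @return character vector of the five file paths, invisibly.
#' @export
write_bulk_import <- function(graph, out_dir) {
  kg_validate(graph)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  put <- function(tbl, headers, file) {
    names(tbl) <- headers
    readr::write_csv(tbl, file.path(out_dir, file), na = "", eol = "\n",
                     progress = FALSE)
    file.path(out_dir, file)
  }
  nodes <- graph$nodes |> arrange(.data$label)
  f1 <- put(tibble(
    nodes$label, nodes$preferred_name,
    join_array(nodes$cuis, "cuis"),
    join_array(nodes$semantic_types, "semanticTypes"),
    join_array(nodes$semantic_groups, "semanticGroups"),
    join_array(nodes$synonyms, "synonyms"),
    "ITEM", .name_repair = "minimal"), BULK_HEADERS$nodes, "nodes.csv")
  texts <- graph$texts |> arrange(.data$text_id)
  f2 <- put(tibble(
    texts$text_id, texts$sentence,
    span_str(texts$head_start, texts$head_end),
    span_str(texts$predicate_start, texts$predicate_end),
    span_str(texts$tail_start, texts$tail_end),
    "TEXT", .name_repair = "minimal"), BULK_HEADERS$texts, "texts.csv")
  docs <- graph$documents |> arrange(.data$document_id)
  f3 <- put(tibble(
    docs$document_id, docs$title, join_array(docs$authors, "authors"),
    docs$journal, docs$publish_date, docs$impact_factor,
    "DOCUMENT", .name_repair = "minimal"), BULK_HEADERS$documents, "documents.csv")
  edges <- graph$edges |>
    arrange(.data$head_label, .data$predicate, .data$tail_label, .data$source)
  f4 <- put(tibble(
    edges$head_label, edges$tail_label, edges$predicate, edges$source,
    edges$weight,
    join_array(lapply(edges$supporting_text_ids, sort), "supportingTextIds"),
    .name_repair = "minimal"), BULK_HEADERS$edges, "edges.csv")
  links <- texts |>
    select(":START_ID" = "text_id", ":END_ID" = "document_id") |>
    mutate(":TYPE" = "IN_DOCUMENT") |>
    arrange(.data$`:START_ID`)
  f5 <- put(links, BULK_HEADERS$in_document, "in_document.csv")
  invisible(c(f1, f2, f3, f4, f5))
}

read_bulk_csv <- function(dir, file, headers) {
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop_litkg(paste0("missing bulk-import file: ", file), "litkg_format_error")
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE,
                         name_repair = "minimal")
  found <- names(tbl)
  if (!identical(found, headers)) {
    off <- which(found != headers[seq_along(found)])[1L] %||% (length(found) + 1L)
    stop_litkg(paste0(file, ": header mismatch at column ", off, " (expected '",
                      headers[min(off, length(headers))], "', found '",
                      found[off] %||% "<none>", "')"), "litkg_format_error")
  }
  tbl
}

#' Read a graph back from the bulk-import CSV dialect
#'
#' Reconstructs a graph equal (in the [kg_equal()] sense) to the one passed
#' to [write_bulk_import()]. Referential problems — an edge endpoint or a
#' supporting-text ID with no corresponding node row — raise integrity
#' errors; header deviations raise format errors naming file and column.
#' Sources whose edges carry supporting texts are registered as literature
#' sources.
#'
#' @param dir directory written by [write_bulk_import()].
#' @return a `knowledge_graph`.
#' @export
read_bulk_import <- function(dir) {
  nodes <- read_bulk_csv(dir, "nodes.csv", BULK_HEADERS$nodes)
  texts <- read_bulk_csv(dir, "texts.csv", BULK_HEADERS$texts)
  docs <- read_bulk_csv(dir, "documents.csv", BULK_HEADERS$documents)
  edges <- read_bulk_csv(dir, "edges.csv", BULK_HEADERS$edges)
  links <- read_bulk_csv(dir, "in_document.csv", BULK_HEADERS$in_document)

  graph <- kg_new(type_to_group = character(), literature_sources = character())
  graph$nodes <- tibble(
    label = nodes[["label:ID"]],
    preferred_name = nodes[["preferredName"]] %||% "",
    cuis = split_array(nodes[["cuis:string[]"]]),
    semantic_types = split_array(nodes[["semanticTypes:string[]"]]),
    semantic_groups = split_array(nodes[["semanticGroups:string[]"]]),
    synonyms = split_array(nodes[["synonyms:string[]"]])
  )
  if (anyDuplicated(graph$nodes$label))
    stop_litkg("nodes.csv: duplicate label:ID", "litkg_integrity_error")

  doc_of <- stats::setNames(links[[":END_ID"]], links[[":START_ID"]])
  if (!all(texts[["text_id:ID"]] %in% names(doc_of)))
    stop_litkg("texts.csv: text without an IN_DOCUMENT link", "litkg_integrity_error")
  hs <- span_unstr(texts[["headSpan"]])
  ps <- span_unstr(texts[["predicateSpan"]])
  ts <- span_unstr(texts[["tailSpan"]])
  graph$texts <- tibble(
    text_id = texts[["text_id:ID"]], sentence = texts[["sentence"]],
    document_id = unname(doc_of[texts[["text_id:ID"]]]),
    head_start = hs[, 1L], head_end = hs[, 2L],
    predicate_start = ps[, 1L], predicate_end = ps[, 2L],
    tail_start = ts[, 1L], tail_end = ts[, 2L]
  )
  graph$documents <- tibble(
    document_id = docs[["document_id:ID"]], title = docs[["title"]] %||% "",
    authors = split_array(docs[["authors:string[]"]]),
    journal = docs[["journal"]] %||% "",
    publish_date = docs[["publishDate"]],
    impact_factor = suppressWarnings(as.numeric(docs[["impactFactor:float"]]))
  )
  graph$documents$title[is.na(graph$documents$title)] <- ""
  graph$documents$journal[is.na(graph$documents$journal)] <- ""

  missing_ep <- setdiff(c(edges[[":START_ID"]], edges[[":END_ID"]]),
                        graph$nodes$label)
  if (length(missing_ep))
    stop_litkg(paste0("edges.csv: unknown endpoint ID(s): ",
                      paste(missing_ep, collapse = ", ")),
               "litkg_integrity_error")
  support <- split_array(edges[["supportingTextIds:string[]"]])
  graph$edges <- tibble(
    edge_id = paste0("E", seq_len(nrow(edges))),
    head_label = edges[[":START_ID"]], tail_label = edges[[":END_ID"]],
    predicate = edges[[":TYPE"]], source = edges[["source"]],
    weight = suppressWarnings(as.numeric(edges[["weight:float"]])),
    supporting_text_ids = support
  )
  graph$edge_counter <- nrow(edges)
  graph$text_counter <- nrow(texts)
  graph$literature_sources <- sort(unique(graph$edges$source[lengths(support) > 0L]))
  kg_validate(graph)
  graph
}

# ---- pipeline --------------------------------------------------------------

#' Read a pipeline configuration file
#'
#' YAML with flat keys: `predications`, `documents` (required file paths);
#' optional `dictionary`, `impact_factors` paths; thresholds
#' `min_entity_score` (default 800), `min_triple_count` (default 2);
#' `literature_source` (default `"CORD19"`); optional `type_groups` mapping
#' of semantic-type code to group name; and a `sources` list whose entries
#' have `name`, `table`, `cui_map` and optional `min_score` (default 0).
#' All thresholds live in the config, never in code, so swapping the whole
#' dataset or the source mix is purely a configuration change.
#'
#' @param path path to a YAML file.
#' @return a validated config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop_litkg(paste0("config file not found: ", path), "litkg_invalid_input")
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg, base_dir = dirname(path))
}

validate_pipeline_config <- function(cfg, base_dir = ".") {
  for (key in c("predications", "documents"))
    if (is.null(cfg[[key]]))
      stop_litkg(paste0("config is missing required key '", key, "'"),
                 "litkg_invalid_input")
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p) && file.exists(file.path(base_dir, p)))
      p <- file.path(base_dir, p)
    if (!file.exists(p))
      stop_litkg(paste0("config references missing file: ", p),
                 "litkg_invalid_input")
    p
  }
  cfg$predications <- resolve(cfg$predications)
  cfg$documents <- resolve(cfg$documents)
  cfg$dictionary <- resolve(cfg$dictionary)
  cfg$impact_factors <- resolve(cfg$impact_factors)
  cfg$min_entity_score <- cfg$min_entity_score %||% 800
  cfg$min_triple_count <- cfg$min_triple_count %||% 2
  cfg$literature_source <- cfg$literature_source %||% "CORD19"
  cfg$type_groups <-
    if (is.null(cfg$type_groups)) default_type_groups() else unlist(cfg$type_groups)
  cfg$sources <- lapply(cfg$sources %||% list(), function(s) {
    for (key in c("name", "table", "cui_map"))
      if (is.null(s[[key]]))
        stop_litkg(paste0("source entry is missing '", key, "'"),
                   "litkg_invalid_input")
    s$table <- resolve(s$table)
    s$cui_map <- resolve(s$cui_map)
    s$min_score <- s$min_score %||% 0
    s
  })
  cfg
}

#' Run the five-stage construction pipeline
#'
#' Executes ingestion, filtration (inferred-predication removal, dictionary
#' normalization, score and occurrence filters, graph construction),
#' provenance registration (text deduplication, article metadata, impact
#' factors), external-source integration, and export (bulk-import CSV under
#' `out_dir/bulk`, native JSON-lines under `out_dir/native`, and a per-stage
#' count log at `out_dir/pipeline_log.tsv`). The log carries no timestamps,
#' so identical configs and inputs produce byte-identical output trees.
#'
#' @param config a config list ([read_pipeline_config()]) or a path to the
#'   YAML file.
#' @param out_dir output directory.
#' @return a list with the final `graph` and the `log` tibble, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else validate_pipeline_config(config)
  log <- list()
  note <- function(stage, metric, value)
    log[[length(log) + 1L]] <<- tibble(stage = stage, metric = metric,
                                       value = as.numeric(value))

  instances <- read_predications(cfg$predications)
  documents <- read_documents(cfg$documents)
  note("ingest", "instances_in", nrow(instances))
  note("ingest", "documents_in", nrow(documents))

  instances <- strip_inferred(instances)
  note("filter", "after_strip_inferred", nrow(instances))
  if (!is.null(cfg$dictionary)) {
    dict <- read_dictionary(cfg$dictionary)
    instances <- normalize_instances(instances, dict)
    note("filter", "dictionary_terms", nrow(dict))
  }
  instances <- filter_instances(instances, cfg$min_entity_score,
                                cfg$min_triple_count)
  note("filter", "surviving_instances", nrow(instances))
  built <- build_graph(instances, type_to_group = cfg$type_groups,
                       source = cfg$literature_source)
  graph <- built$graph
  note("filter", "nodes", nrow(graph$nodes))
  note("filter", "unique_triples", nrow(graph$edges))

  graph <- register_texts(graph, built$text_drafts, documents)
  note("metadata", "unique_texts", nrow(graph$texts))
  note("metadata", "documents_registered", nrow(graph$documents))
  if (!is.null(cfg$impact_factors)) {
    graph <- attach_impact_factors(graph, read_impact_factors(cfg$impact_factors))
    note("metadata", "impact_factors_attached", attr(graph, "n_attached"))
  }

  note("integrate", "density_before", kg_density(graph))
  for (s in cfg$sources) {
    rows <- read_source_table(s$table, s$name)
    cmap <- read_cui_map(s$cui_map)
    graph <- integrate_source(graph, rows, cmap, min_score = s$min_score)
    rep <- utils::tail(integration_report(graph), 1L)
    note("integrate", paste0(s$name, "_rows_seen"), rep$rows_seen)
    note("integrate", paste0(s$name, "_edges_added"), rep$edges_added)
  }
  note("integrate", "density_after", kg_density(graph))

  kg_validate(graph)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_bulk_import(graph, file.path(out_dir, "bulk"))
  kg_write_jsonl(graph, file.path(out_dir, "native"))
  note("export", "final_nodes", nrow(graph$nodes))
  note("export", "final_edges", nrow(graph$edges))
  note("export", "final_texts", nrow(graph$texts))
  note("export", "final_documents", nrow(graph$documents))
  log_tbl <- bind_rows(log)
  readr::write_tsv(log_tbl, file.path(out_dir, "pipeline_log.tsv"),
                   progress = FALSE)
  invisible(list(graph = graph, log = log_tbl))
}
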