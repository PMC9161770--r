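# Stage 2: reduce raw predication instances to high-quality triples and build
# the initial literature graph. Order matters and is fixed: strip inferred
# predications, normalize designated terminology (so surface variants pool
# their occurrence counts), apply the entity-confidence filter, then the
# triple-occurrence filter computed on the score survivors.

#' Drop inferred and speculative predications
#'
#' Removes every instance whose predicate carries an `"(INFER)"` or
#' `"(SPEC)"` suffix. These mark relationships inferred from other extracted
#' predications rather than asserted in the sentence itself.
#'
#' @param instances a tibble of triple instances ([read_predications()]).
#' @return the surviving instances, order preserved.
#' @export
strip_inferred <- function(instances) {
  filter(instances, !grepl("\\((INFER|SPEC)\\)$", .data$predicate))
}

# longest dictionary term contained in each surface; ties broken by earliest
# match position, then lexicographically smallest term. Returns the matched
# subject per surface (NA when no term matches).
match_dictionary <- function(surfaces, dictionary) {
  out <- rep(NA_character_, length(surfaces))
  if (!nrow(dictionary) || !length(surfaces)) return(out)
  low <- tolower(surfaces)
  best_len <- rep(-1L, length(surfaces))
  best_pos <- rep(.Machine$integer.max, length(surfaces))
  best_term <- rep(NA_character_, length(surfaces))
  ord <- order(-nchar(dictionary$term), dictionary$term, method = "radix")
  for (i in ord) {
    term <- dictionary$term[i]
    pos <- stringr::str_locate(low, stringr::fixed(term))[, 1L]
    len <- nchar(term)
    better <- !is.na(pos) &
      (len > best_len | (len == best_len & pos < best_pos))
    if (any(better)) {
      best_len[better] <- len
      best_pos[better] <- pos[better]
      best_term[better] <- term
      out[better] <- dictionary$subject[match(term, dictionary$term)]
    }
  }
  out
}

#' Normalize designated terminology in triple instances
#'
#' For each instance and each of head/tail: if the lower-cased surface form
#' contains a dictionary term, the entity's normalized name is replaced by the
#' dictionary's subject label and its CUI is cleared (the subject is a
#' dictionary-defined label, not a Metathesaurus concept). The longest
#' matching term wins; ties are broken by earliest match position. The original
#' surface form is retained and later recorded as a node synonym by
#' [build_graph()].
#'
#' @param instances a tibble of triple instances.
#' @param dictionary a tibble from [read_dictionary()].
#' @return the instances with `head_name`/`tail_name` (and CUIs) rewritten
#'   where a term matched.
#' @export
normalize_instances <- function(instances, dictionary) {
  if (!nrow(instances) || !nrow(dictionary)) return(instances)
  for (side in c("head", "tail")) {
    subj <- match_dictionary(instances[[paste0(side, "_surface")]], dictionary)
    hit <- !is.na(subj)
    instances[[paste0(side, "_name")]][hit] <- subj[hit]
    instances[[paste0(side, "_cui")]][hit] <- ""
  }
  instances
}

#' Filter instances by entity confidence and triple occurrence
#'
#' Two sequential filters: first, instances where either entity's extraction
#' confidence score is below `min_entity_score` are dropped; then occurrence
#' counts of each unique (head, predicate, tail) triple are computed *among
#' the score survivors*, and triples occurring fewer than `min_triple_count`
#' times are dropped. The defaults (score 800 of 1000, at least 2 occurrences)
#' keep only high-confidence, recurrent relationships.
#'
#' @param instances a tibble of triple instances.
#' @param min_entity_score minimum per-entity confidence score (0-1000).
#' @param min_triple_count minimum occurrences of a unique triple.
#' @return the surviving instances, order preserved.
#' @export
filter_instances <- function(instances, min_entity_score = 800,
                             min_triple_count = 2) {
  if (min_entity_score < 0 || min_triple_count < 0)
    stop_litkg("thresholds must be non-negative", "litkg_invalid_input")
  survivors <- filter(instances,
                      .data$head_score >= min_entity_score,
                      .data$tail_score >= min_entity_score)
  survivors |>
    dplyr::add_count(.data$head_name, .data$predicate, .data$tail_name,
                     name = "..triple_n") |>
    filter(.data$..triple_n >= min_triple_count) |>
    select(-"..triple_n")
}

#' Build the initial literature knowledge graph
#'
#' Constructs one concept node per distinct normalized entity name (CUIs,
#' semantic types, derived groups and surface-form synonyms unioned over all
#' instances mentioning it) and one literature edge per unique
#' (head, predicate, tail) triple, weighted by the number of instances and
#' carrying one draft supporting-text ID per instance. Text drafts are
#' deduplicated later by [register_texts()], which also recomputes weights.
#'
#' @param instances filtered triple instances ([filter_instances()]).
#' @param type_to_group named character vector mapping semantic-type codes to
#'   group names; see [kg_new()].
#' @param source source name recorded on the literature edges.
#' @return a list with elements `graph` (a `knowledge_graph`) and
#'   `text_drafts` (a tibble of per-instance supporting-sentence drafts).
#' @export
build_graph <- function(instances, type_to_group = default_type_groups(),
                        source = "CORD19") {
  graph <- kg_new(type_to_group = type_to_group, literature_sources = source)
  if (!nrow(instances))
    return(list(graph = graph, text_drafts = empty_texts()))

  side_nodes <- function(side) {
    tibble(
      label = instances[[paste0(side, "_name")]],
      preferred_name = instances[[paste0(side, "_name")]],
      cuis = lapply(instances[[paste0(side, "_cui")]], as_set),
      semantic_types = lapply(instances[[paste0(side, "_types")]], as_set),
      synonyms = lapply(instances[[paste0(side, "_surface")]], as_set)
    )
  }
  graph <- upsert_nodes_tbl(graph, bind_rows(side_nodes("head"), side_nodes("tail")))

  draft_ids <- paste0("T", seq_len(nrow(instances)))
  text_drafts <- tibble(
    text_id = draft_ids,
    sentence = instances$sentence,
    document_id = instances$document_id,
    head_start = instances$head_start, head_end = instances$head_end,
    predicate_start = NA_integer_, predicate_end = NA_integer_,
    tail_start = instances$tail_start, tail_end = instances$tail_end
  )

  key <- paste(instances$head_name, instances$predicate, instances$tail_name,
               sep = "\r")
  first_seen <- match(unique(key), key)
  grouped <- split(draft_ids, factor(key, levels = key[first_seen]))
  graph$edges <- tibble(
    edge_id = paste0("E", seq_along(first_seen)),
    head_label = instances$head_name[first_seen],
    tail_label = instances$tail_name[first_seen],
    predicate = instances$predicate[first_seen],
    source = source,
    weight = as.numeric(lengths(grouped)),
    supporting_text_ids = unname(grouped)
  )
  graph$edge_counter <- length(first_seen)
  list(graph = graph, text_drafts = text_drafts)
}
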