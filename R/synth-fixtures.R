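# Seeded generator of synthetic predication corpora and external source
# tables, with ground-truth manifests. Sentences are templated so that head
# and tail surfaces appear verbatim at the recorded spans, which makes the
# provenance round trip assertable as literal substring containment. The same
# seed always yields byte-identical files.

# scoped RNG: seeds deterministically, restores the caller's RNG state on exit
local_rng <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  expr <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = env)
  set.seed(seed)
}

ENTITY_KINDS <- tibble::tibble(
  prefix = c("GENE", "DRUG", "DIS"),
  type = c("gngm", "phsu", "dsyn")
)

PREDICATE_POOL <- c("TREATS", "CAUSES", "INHIBITS", "INTERACTS_WITH",
                    "AFFECTS", "PREDISPOSES")

JOURNAL_POOL <- c("Journal of Synthetic Medicine", "Annals of Test Biology",
                  "Fixture Reports", "Molecular Fixtures",
                  "Archives of Generated Science", "Synthetic Lancet")

AUTHOR_POOL <- c("Garcia A", "Chen B", "Okafor C", "Muller D", "Rossi E",
                 "Tanaka F", "Novak G", "Silva H")

# The trailing report tag makes each generated sentence globally unique, so
# only deliberately copied instances ever share a (document, sentence) pair.
make_sentence <- function(head_surface, predicate, tail_surface, tag) {
  verb <- gsub("_", " ", tolower(sub("\\((INFER|SPEC)\\)$", "", predicate)))
  sentence <- paste0("In this study, ", head_surface, " ", verb, " ",
                     tail_surface, " according to report ", tag, ".")
  h0 <- nchar("In this study, ")
  list(
    sentence = sentence,
    head_start = h0, head_end = h0 + nchar(head_surface),
    tail_start = h0 + nchar(head_surface) + 1L + nchar(verb) + 1L,
    tail_end = h0 + nchar(head_surface) + 1L + nchar(verb) + 1L + nchar(tail_surface)
  )
}

sample_distinct_pairs <- function(n_pairs, labels, exclude = character()) {
  n <- length(labels)
  capacity <- n * (n - 1L)
  if (n_pairs + length(exclude) > capacity)
    stop_litkg("not enough distinct entity pairs for the requested counts",
               "litkg_invalid_input")
  taken <- exclude
  out_h <- character(n_pairs); out_t <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    repeat {
      ht <- sample(labels, 2L)
      key <- paste(ht[1L], ht[2L], sep = "\r")
      if (!key %in% taken) break
    }
    taken <- c(taken, key)
    out_h[i] <- ht[1L]; out_t[i] <- ht[2L]
  }
  tibble(head = out_h, tail = out_t)
}

#' Generate a synthetic predication corpus with ground truth
#'
#' Emits a predication file, an article metadata table, a normalization
#' dictionary, a journal impact-factor table, and a manifest recording exactly
#' what was planted. Planted triples receive at least two instances with
#' entity scores of at least 800, so they survive the default filtration;
#' noise comes in three flavors that each stage must remove: instances with a
#' sub-threshold entity score, singleton triples, and inferred/speculative
#' predications. A configurable number of planted triples use head surface
#' variants that only pool into one triple after dictionary normalization.
#' Some instance pairs share their (document, sentence) so text deduplication
#' is exercised.
#'
#' @param seed integer seed; identical seeds yield byte-identical files.
#' @param n_documents,n_entities,n_planted_triples positive sizes
#'   (`n_entities >= 2`).
#' @param noise list with counts `n_low_score`, `n_singleton`, `n_inferred`,
#'   `n_variant_triples`.
#' @param dir output directory (created if needed).
#' @return the manifest, a list with the planted-triple table
#'   (`planted_triples`: head, predicate, tail, intended_instance_count,
#'   deduped_text_count), noise counts, `expected_survivors_after_filter`
#'   (instances), `expected_unique_triples`, `expected_nodes`,
#'   `expected_unique_texts`, and the emitted file paths.
#' @export
generate_corpus <- function(seed, n_documents = 20L, n_entities = 30L,
                            n_planted_triples = 10L,
                            noise = list(n_low_score = 15L, n_singleton = 10L,
                                         n_inferred = 8L, n_variant_triples = 2L),
                            dir = tempfile("corpus")) {
  if (n_documents < 1L || n_planted_triples < 1L)
    stop_litkg("all counts must be positive", "litkg_invalid_input")
  if (n_entities < 2L)
    stop_litkg("need at least two entities to form head/tail pairs",
               "litkg_invalid_input")
  noise <- utils::modifyList(
    list(n_low_score = 0L, n_singleton = 0L, n_inferred = 0L,
         n_variant_triples = 0L), noise)
  if (noise$n_variant_triples > n_planted_triples)
    stop_litkg("n_variant_triples cannot exceed n_planted_triples",
               "litkg_invalid_input")
  local_rng(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  kind <- ENTITY_KINDS[rep_len(seq_len(nrow(ENTITY_KINDS)), n_entities), ]
  entities <- tibble(
    label = paste0(kind$prefix, seq_len(n_entities)),
    cui = sprintf("C%07d", 1000000L + seq_len(n_entities)),
    type = kind$type
  )

  planted <- sample_distinct_pairs(n_planted_triples, entities$label)
  planted$predicate <- sample(PREDICATE_POOL, n_planted_triples, replace = TRUE)
  planted$intended_instance_count <- sample(2:4, n_planted_triples, replace = TRUE)
  planted$variant <- seq_len(n_planted_triples) <= noise$n_variant_triples

  dictionary <- purrr::map_dfr(unique(planted$head[planted$variant]),
                               function(h) {
    tibble(term = tolower(paste(h, "variant", 1:2)), subject = h)
  })

  # rows are accumulated as plain lists (type fields as scalar strings) and
  # materialized once at the end; a per-instance tibble would dominate runtime
  tail_cui_of <- stats::setNames(entities$cui, entities$label)
  tail_type_of <- stats::setNames(entities$type, entities$label)
  instance_row <- function(doc, sid, head_surface, head_cui, head_name,
                           head_type, head_score, predicate, tail_label,
                           tail_score) {
    s <- make_sentence(head_surface, predicate, tail_label, sid)
    list(
      document_id = doc, sentence_id = sid, sentence = s$sentence,
      head_surface = head_surface, head_cui = head_cui, head_name = head_name,
      head_types = head_type, head_score = head_score,
      head_start = s$head_start, head_end = s$head_end,
      predicate = predicate,
      tail_surface = tail_label, tail_cui = unname(tail_cui_of[tail_label]),
      tail_name = tail_label,
      tail_types = unname(tail_type_of[tail_label]), tail_score = tail_score,
      tail_start = s$tail_start, tail_end = s$tail_end
    )
  }

  doc_ids <- sprintf("DOC%04d", seq_len(n_documents))
  sid <- 0L
  rows <- list()
  planted$deduped_text_count <- 0L
  for (i in seq_len(n_planted_triples)) {
    ent_h <- entities[match(planted$head[i], entities$label), ]
    n_inst <- planted$intended_instance_count[i]
    share_prev <- c(FALSE, stats::runif(n_inst - 1L) < 0.3)  # duplicate sentences
    planted$deduped_text_count[i] <- sum(!share_prev)
    prev <- NULL
    for (k in seq_len(n_inst)) {
      if (planted$variant[i]) {
        variant_k <- ((k - 1L) %% 2L) + 1L
        head_surface <- paste(planted$head[i], "variant", variant_k)
        head_name <- head_surface     # unnormalized until the dictionary runs
        head_cui <- sprintf("C%07d", 8000000L + 10L * i + variant_k)
      } else {
        head_surface <- planted$head[i]
        head_name <- planted$head[i]
        head_cui <- ent_h$cui
      }
      if (share_prev[k] && !is.null(prev) && !planted$variant[i]) {
        row <- prev   # same document & sentence: exercises text deduplication
      } else {
        sid <- sid + 1L
        row <- instance_row(sample(doc_ids, 1L), paste0("S", sid),
                            head_surface, head_cui, head_name, ent_h$type,
                            sample(800:1000, 1L), planted$predicate[i],
                            planted$tail[i], sample(800:1000, 1L))
        prev <- row
      }
      rows[[length(rows) + 1L]] <- row
    }
    if (planted$variant[i])
      planted$deduped_text_count[i] <- n_inst  # variant surfaces never collide
  }

  planted_keys <- paste(planted$head, planted$tail, sep = "\r")
  if (noise$n_singleton > 0L) {
    singles <- sample_distinct_pairs(noise$n_singleton, entities$label,
                                     exclude = planted_keys)
    for (i in seq_len(noise$n_singleton)) {
      sid <- sid + 1L
      ent_h <- entities[match(singles$head[i], entities$label), ]
      rows[[length(rows) + 1L]] <- instance_row(
        sample(doc_ids, 1L), paste0("S", sid), singles$head[i], ent_h$cui,
        singles$head[i], ent_h$type, sample(800:1000, 1L),
        sample(PREDICATE_POOL, 1L), singles$tail[i], sample(800:1000, 1L))
    }
  }
  if (noise$n_low_score > 0L) {
    for (i in seq_len(noise$n_low_score)) {
      sid <- sid + 1L
      pair <- sample(entities$label, 2L)
      ent_h <- entities[match(pair[1L], entities$label), ]
      low_head <- stats::runif(1) < 0.5
      rows[[length(rows) + 1L]] <- instance_row(
        sample(doc_ids, 1L), paste0("S", sid), pair[1L], ent_h$cui, pair[1L],
        ent_h$type, if (low_head) sample(100:799, 1L) else sample(800:1000, 1L),
        "NOISE_LOW", pair[2L],
        if (low_head) sample(800:1000, 1L) else sample(100:799, 1L))
    }
  }
  if (noise$n_inferred > 0L) {
    for (i in seq_len(noise$n_inferred)) {
      sid <- sid + 1L
      pair <- sample(entities$label, 2L)
      ent_h <- entities[match(pair[1L], entities$label), ]
      suffix <- if (i %% 2L) "(INFER)" else "(SPEC)"
      rows[[length(rows) + 1L]] <- instance_row(
        sample(doc_ids, 1L), paste0("S", sid), pair[1L], ent_h$cui, pair[1L],
        ent_h$type, sample(800:1000, 1L),
        paste0(sample(PREDICATE_POOL, 1L), suffix), pair[2L],
        sample(800:1000, 1L))
    }
  }

  instances <- bind_rows(rows[sample.int(length(rows))]) |>
    mutate(head_types = strsplit(.data$head_types, "|", fixed = TRUE),
           tail_types = strsplit(.data$tail_types, "|", fixed = TRUE))

  documents <- tibble(
    document_id = doc_ids,
    title = paste("Synthetic study", seq_len(n_documents), "of generated corpora"),
    authors = lapply(seq_len(n_documents),
                     function(i) sample(AUTHOR_POOL, sample(1:3, 1L))),
    journal = sample(JOURNAL_POOL, n_documents, replace = TRUE),
    publish_date = sprintf("2020-%02d-%02d", sample(1:12, n_documents, TRUE),
                           sample(1:28, n_documents, TRUE))
  )
  # impact factors for four of the six journals, with case/space jitter to
  # exercise the normalized matching
  jif <- tibble(
    journal = c(toupper(JOURNAL_POOL[1L]), paste0(" ", JOURNAL_POOL[2L], " "),
                tolower(JOURNAL_POOL[3L]), JOURNAL_POOL[4L]),
    impact_factor = round(stats::runif(4L, 1, 50), 1)
  )

  paths <- list(
    predications = file.path(dir, "predications.tsv"),
    documents = file.path(dir, "documents.tsv"),
    dictionary = file.path(dir, "dictionary.tsv"),
    jif = file.path(dir, "jif.tsv")
  )
  write_predications(instances, paths$predications)
  write_documents(documents, paths$documents)
  if (nrow(dictionary)) write_dictionary(dictionary, paths$dictionary)
  else writeLines(c(tsv_version_line("dictionary"), "term\tsubject"),
                  paths$dictionary)
  write_impact_factors(jif, paths$jif)

  # survivors: normalized planted instances; unique texts among them
  surv_texts <- sum(planted$deduped_text_count)
  manifest <- list(
    seed = seed, n_documents = n_documents, n_entities = n_entities,
    planted_triples = planted |>
      mutate(head_normalized = .data$head) |>
      select("head", "predicate", "tail", "intended_instance_count",
             "variant", "deduped_text_count"),
    n_low_score_instances = noise$n_low_score,
    n_singleton_triples = noise$n_singleton,
    n_inferred_instances = noise$n_inferred,
    n_instances_total = nrow(instances),
    expected_survivors_after_filter = sum(planted$intended_instance_count),
    expected_unique_triples = n_planted_triples,
    expected_nodes = length(unique(c(planted$head, planted$tail))),
    expected_unique_texts = surv_texts,
    files = paths
  )
  manifest_out <- manifest
  manifest_out$planted_triples <- purrr::transpose(manifest$planted_triples)
  jsonlite::write_json(manifest_out, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Generate an external source table and CUI map for a graph
#'
#' Splits rows between mappable (both keys resolve through the emitted CUI map
#' to CUIs carried by graph nodes) and unmappable (a key absent from the map,
#' or a key mapping to a CUI no node carries), and records the split in the
#' manifest. Mappable rows use distinct ordered node pairs, so with
#' `min_score = 0` the number of edges added by [integrate_source()] equals
#' the mappable count.
#'
#' @param seed integer seed.
#' @param graph a `knowledge_graph` whose CUI-bearing nodes are the targets.
#' @param n_rows total rows to emit.
#' @param fraction_mappable fraction of rows (rounded down) that must map.
#' @param source_name recorded source name (e.g. `"STRING"`).
#' @param relation relation type on every row.
#' @param score_range numeric `c(lo, hi)`; scores drawn uniformly and rounded.
#' @param dir output directory.
#' @return manifest list with counts and file paths (`source`, `cui_map`).
#' @export
generate_source_tables <- function(seed, graph, n_rows = 30L,
                                   fraction_mappable = 0.7,
                                   source_name = "STRING",
                                   relation = "ASSOCIATED_DB",
                                   score_range = c(100, 1000),
                                   dir = tempfile("sources")) {
  stopifnot(inherits(graph, "knowledge_graph"))
  pool <- graph$nodes$label[lengths(graph$nodes$cuis) > 0L]
  if (!length(pool))
    stop_litkg("graph has no CUI-bearing nodes to map onto", "litkg_invalid_input")
  if (length(pool) < 2L)
    stop_litkg("need at least two CUI-bearing nodes", "litkg_invalid_input")
  local_rng(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  n_mappable <- floor(n_rows * fraction_mappable)
  n_unmappable <- n_rows - n_mappable
  n_unmapped_key <- ceiling(n_unmappable / 2)
  n_absent_node <- n_unmappable - n_unmapped_key

  first_cui <- vapply(graph$nodes$cuis[match(pool, graph$nodes$label)],
                      `[`, character(1), 1L)
  cui_map <- tibble(key = paste0("K_", pool), cui = first_cui)

  rows <- list()
  if (n_mappable > 0L) {
    pairs <- sample_distinct_pairs(n_mappable, pool)
    rows$mappable <- tibble(key_a = paste0("K_", pairs$head),
                            key_b = paste0("K_", pairs$tail))
  }
  if (n_unmapped_key > 0L)
    rows$unmapped <- tibble(
      key_a = paste0("UNKNOWN_", seq_len(n_unmapped_key)),
      key_b = paste0("K_", sample(pool, n_unmapped_key, replace = TRUE)))
  if (n_absent_node > 0L) {
    ghost_keys <- paste0("GHOST_", seq_len(n_absent_node))
    cui_map <- bind_rows(cui_map, tibble(
      key = ghost_keys, cui = sprintf("C%07d", 9900000L + seq_len(n_absent_node))))
    rows$ghost <- tibble(
      key_a = ghost_keys,
      key_b = paste0("K_", sample(pool, n_absent_node, replace = TRUE)))
  }
  table <- bind_rows(rows) |>
    mutate(relation = relation,
           score = round(stats::runif(dplyr::n(), score_range[1L], score_range[2L])))
  if (nrow(table)) table <- table[sample.int(nrow(table)), , drop = FALSE]

  paths <- list(source = file.path(dir, paste0(tolower(source_name), ".tsv")),
                cui_map = file.path(dir, "cui_map.tsv"))
  write_source_table(table, paths$source)
  write_cui_map(cui_map, paths$cui_map)
  manifest <- list(
    seed = seed, source = source_name, n_rows = n_rows,
    n_mappable = n_mappable, n_unmapped_key = n_unmapped_key,
    n_absent_node = n_absent_node,
    expected_edges_added = n_mappable,
    files = paths
  )
  jsonlite::write_json(manifest, file.path(dir, "sources_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
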