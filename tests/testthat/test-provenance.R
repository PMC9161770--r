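docs_tbl <- function(ids = c("DOC1", "DOC2")) {
  tibble::tibble(document_id = ids, title = paste("Title", ids),
                 authors = rep(list("Garcia A"), length(ids)),
                 journal = c("The Lancet", "Fixture Reports")[seq_along(ids)],
                 publish_date = "2020-06")
}

test_that("register_texts deduplicates by (document, sentence) and rewrites edges", {
  inst <- dplyr::bind_rows(
    make_instances("A", "TREATS", "B"),
    make_instances("A", "AFFECTS", "C"))
  # both instances extracted from the same sentence of the same abstract
  inst$sentence <- "A treats B and affects C."
  inst$sentence_id <- c("S1", "S1")
  inst$head_end <- 1L; inst$tail_start <- 9L; inst$tail_end <- 10L
  built <- build_graph(inst)
  g <- register_texts(built$graph, built$text_drafts, docs_tbl())
  expect_equal(nrow(g$texts), 1L)
  expect_equal(unlist(g$edges$supporting_text_ids), c("T1", "T1"),
               ignore_attr = TRUE)
  expect_equal(g$edges$weight, c(1, 1))

  # same sentence string in two different documents stays two records
  inst2 <- make_instances("A", "TREATS", "B", n = 2)
  inst2$sentence <- "A treats B."
  inst2$document_id <- c("DOC1", "DOC2")
  inst2$head_end <- 1L; inst2$tail_start <- 9L; inst2$tail_end <- 10L
  built2 <- build_graph(inst2)
  g2 <- register_texts(built2$graph, built2$text_drafts, docs_tbl())
  expect_equal(nrow(g2$texts), 2L)
  expect_equal(g2$edges$weight, 2)

  # only referenced documents are registered
  expect_equal(g2$documents$document_id, c("DOC1", "DOC2"))
  expect_equal(g$documents$document_id, "DOC1")

  # empty drafts leave the graph unchanged
  g3 <- register_texts(built2$graph, built2$text_drafts[0, ], docs_tbl())
  expect_true(kg_equal(g3, built2$graph))

  bad_drafts <- built2$text_drafts
  bad_drafts$document_id[1] <- "GHOST"
  expect_error(register_texts(built2$graph, bad_drafts, docs_tbl()),
               class = "litkg_missing_document")
})

test_that("weight equals the supporting-text count for every literature edge after registration", {
  fx <- build_fixture_graph(11)
  e <- fx$graph$edges
  lit <- e$source %in% fx$graph$literature_sources
  expect_true(all(lit))
  expect_equal(e$weight, as.numeric(lengths(e$supporting_text_ids)))
})

test_that("impact factors match case-insensitively with whitespace normalization", {
  inst <- make_instances("A", "TREATS", "B")
  inst$head_end <- 1L; inst$tail_start <- 9L; inst$tail_end <- 10L
  inst$sentence <- "A treats B."
  built <- build_graph(inst)
  g <- register_texts(built$graph, built$text_drafts, docs_tbl("DOC1"))

  g1 <- attach_impact_factors(g, tibble::tibble(journal = "the  lancet",
                                                impact_factor = 60.4))
  expect_equal(attr(g1, "n_attached"), 1L)
  expect_equal(g1$documents$impact_factor, 60.4)

  g2 <- attach_impact_factors(g, tibble::tibble(journal = "Nature",
                                                impact_factor = 50))
  expect_equal(attr(g2, "n_attached"), 0L)
  expect_true(is.na(g2$documents$impact_factor))

  g3 <- attach_impact_factors(g, tibble::tibble(journal = character(),
                                                impact_factor = double()))
  expect_equal(attr(g3, "n_attached"), 0L)
})

test_that("supporting_evidence returns ordered text/article pairs and catches corruption", {
  g0 <- make_g0()
  eid <- edge_id_of(g0, "A", "TREATS", "B", "CORD19")
  ev <- supporting_evidence(g0, eid)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$text_id, c("T1", "T2", "T3"))  # stored order
  expect_equal(ev$journal[1], "Synthetic Lancet")

  string_edge <- edge_id_of(g0, "B", "INTERACTS_WITH", "C", "STRING")
  expect_equal(nrow(supporting_evidence(g0, string_edge)), 0L)

  expect_error(supporting_evidence(g0, "E999"), class = "litkg_missing_edge")

  corrupted <- g0
  corrupted$texts <- corrupted$texts[-1, ]
  expect_error(supporting_evidence(corrupted, eid),
               class = "litkg_integrity_error")
})

test_that("every evidence sentence contains a recorded surface of both endpoints", {
  fx <- build_fixture_graph(23)
  g <- fx$graph
  for (i in seq_len(nrow(g$edges))) {
    ev <- supporting_evidence(g, g$edges$edge_id[i])
    head_surfaces <- c(g$edges$head_label[i],
                       g$nodes$synonyms[[match(g$edges$head_label[i],
                                               g$nodes$label)]])
    tail_surfaces <- c(g$edges$tail_label[i],
                       g$nodes$synonyms[[match(g$edges$tail_label[i],
                                               g$nodes$label)]])
    for (s in ev$sentence) {
      expect_true(any(vapply(head_surfaces, grepl, logical(1), x = s,
                             fixed = TRUE)))
      expect_true(any(vapply(tail_surfaces, grepl, logical(1), x = s,
                             fixed = TRUE)))
    }
  }
})

test_that("dates are parsed leniently and stored normalized", {
  g <- kg_new()
  g <- add_document(g, "D1", publish_date = "2020")
  g <- add_document(g, "D2", publish_date = "2020-3")
  g <- add_document(g, "D3", publish_date = "2020-03-09")
  expect_equal(g$documents$publish_date, c("2020", "2020-03", "2020-03-09"))
  expect_error(add_document(g, "D4", publish_date = "not a date"),
               class = "litkg_invalid_input")
})
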