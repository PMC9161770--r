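test_that("upsert_node merges by set union, keeps first preferred name, is idempotent", {
  g <- kg_new()
  g <- upsert_node(g, "ACE2", preferred_name = "ACE2 protein", cuis = "C1")
  g <- upsert_node(g, "ACE2", preferred_name = "other name", cuis = "C2",
                   semantic_types = "gngm", synonyms = "ace-2")
  expect_equal(nrow(g$nodes), 1L)
  expect_setequal(g$nodes$cuis[[1]], c("C1", "C2"))
  expect_equal(g$nodes$preferred_name, "ACE2 protein")
  expect_equal(g$nodes$semantic_groups[[1]], "Genes & Molecular Sequences")
  expect_setequal(g$nodes$synonyms[[1]], "ace-2")

  twice <- upsert_node(g, "ACE2", cuis = "C2", semantic_types = "gngm",
                       synonyms = "ace-2")
  expect_true(kg_equal(g, twice))

  g2 <- upsert_node(g, "TMPRSS2")
  expect_equal(nrow(g2$nodes), 2L)
  expect_error(upsert_node(g, ""), class = "litkg_invalid_input")
})

test_that("add_edge merges literature edges by text union and database edges by max weight", {
  g <- kg_new()
  g <- upsert_node(g, "HCQ")
  g <- upsert_node(g, "COVID-19")
  g <- add_document(g, "DOC1")
  g <- add_text(g, "HCQ treats COVID-19 maybe.", "DOC1")
  g <- add_text(g, "HCQ treats COVID-19 again.", "DOC1")
  g <- add_edge(g, "HCQ", "TREATS", "COVID-19", "CORD19",
                supporting_text_ids = "T1")
  g <- add_edge(g, "HCQ", "TREATS", "COVID-19", "CORD19",
                supporting_text_ids = "T2")
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 2)
  expect_setequal(g$edges$supporting_text_ids[[1]], c("T1", "T2"))

  g <- add_edge(g, "HCQ", "INTERACTS_WITH", "COVID-19", "STRING", weight = 700)
  g <- add_edge(g, "HCQ", "INTERACTS_WITH", "COVID-19", "STRING", weight = 900)
  e <- g$edges[g$edges$source == "STRING", ]
  expect_equal(nrow(e), 1L)
  expect_equal(e$weight, 900)

  expect_error(add_edge(g, "UNKNOWN", "TREATS", "COVID-19", "CORD19"),
               class = "litkg_missing_node")
  expect_no_error(kg_validate(g))
})

test_that("density uses unique directed triples over ordered pairs", {
  # complete directed graph on 3 nodes
  g <- kg_new(literature_sources = character())
  for (lab in c("X", "Y", "Z")) g <- upsert_node(g, lab)
  for (h in c("X", "Y", "Z")) for (t in setdiff(c("X", "Y", "Z"), h))
    g <- add_edge(g, h, "REL", t, "SRC", weight = 1)
  expect_equal(kg_density(g), 1.0)

  g1 <- upsert_node(kg_new(), "solo")
  expect_equal(kg_density(g1), 0.0)
  expect_equal(kg_density(kg_new()), 0.0)

  expect_equal(kg_density(make_g0()), 5 / 20)
})

test_that("density ignores source multiplicity and node insertion order", {
  g <- make_g0()
  before <- kg_density(g)
  g <- add_edge(g, "B", "INTERACTS_WITH", "C", "DISGENET", weight = 1)
  expect_equal(kg_density(g), before)  # parallel source, same triple

  # same structure, nodes inserted in reverse order
  g2 <- kg_new(literature_sources = character())
  for (lab in rev(c("A", "B", "C", "D", "E"))) g2 <- upsert_node(g2, lab)
  edges <- list(c("A", "B"), c("B", "C"), c("C", "D"), c("A", "D"), c("D", "E"))
  for (e in edges) g2 <- add_edge(g2, e[1], "REL", e[2], "SRC", weight = 1)
  expect_equal(kg_density(g2), 5 / 20)
})

test_that("referential integrity holds after interleaved mutations and validate catches corruption", {
  set.seed(42)
  g <- kg_new(literature_sources = character())
  labels <- sprintf("N%d", 1:8)
  for (i in 1:60) {
    if (runif(1) < 0.4 || nrow(g$nodes) < 2) {
      g <- upsert_node(g, sample(labels, 1),
                       cuis = sample(sprintf("C%d", 1:5), 1))
    } else {
      ht <- sample(g$nodes$label, 2)
      g <- add_edge(g, ht[1], "REL", ht[2], sample(c("S1", "S2"), 1),
                    weight = runif(1, 0, 10))
    }
  }
  expect_no_error(kg_validate(g))

  broken <- g
  broken$nodes <- broken$nodes[-1, ]
  if (any(broken$edges$head_label == g$nodes$label[1] |
          broken$edges$tail_label == g$nodes$label[1]))
    expect_error(kg_validate(broken), class = "litkg_integrity_error")

  broken2 <- make_g0()
  broken2$edges$supporting_text_ids[[1]] <-
    c(broken2$edges$supporting_text_ids[[1]], "T999")
  expect_error(kg_validate(broken2), class = "litkg_integrity_error")
})

test_that("text spans must stay inside the sentence and not overlap", {
  g <- add_document(kg_new(), "DOC1")
  expect_error(add_text(g, "short.", "DOC1", head_span = c(0, 99)),
               class = "litkg_invalid_input")
  expect_error(add_text(g, "abcdef.", "DOC1", head_span = c(0, 4),
                        tail_span = c(3, 6)),
               class = "litkg_invalid_input")
  expect_error(add_text(g, "", "DOC1"), class = "litkg_invalid_input")
  expect_error(add_text(g, "fine.", "NOPE"), class = "litkg_missing_document")
  g <- add_text(g, "abc def.", "DOC1", head_span = c(0, 3), tail_span = c(4, 7))
  expect_equal(g$texts$head_end, 3L)
})

test_that("native JSON-lines serialization round-trips a graph", {
  g <- make_g0()
  dir <- tempfile("jsonl")
  kg_write_jsonl(g, dir)
  g2 <- kg_read_jsonl(dir)
  expect_true(kg_equal(g, g2))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$n_nodes, 5L)
  expect_equal(manifest$n_edges, 5L)
})

test_that("tidy and glance summarize the store", {
  g <- make_g0()
  td <- tidy(g)
  expect_equal(nrow(td), 5L)
  expect_equal(td$n_supporting_texts[td$predicate == "TREATS" &
                                     td$head_label == "A"], 3L)
  gl <- glance(g)
  expect_equal(gl$n_nodes, 5L)
  expect_equal(gl$n_unique_triples, 5L)
  expect_equal(gl$density, 0.25)
})
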