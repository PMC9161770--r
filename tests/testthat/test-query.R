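test_that("direct search honours predicates, direction and per-source thresholds", {
  g0 <- make_g0()
  res <- direct_search(g0, "A", "B",
                       query_options(predicates = "TREATS"))
  expect_equal(nrow(res), 1L)
  expect_equal(nrow(res$evidence[[1]]), 3L)

  expect_equal(nrow(direct_search(g0, "B", "A",
                                  query_options(direction = "outgoing"))), 0L)
  expect_equal(nrow(direct_search(g0, "B", "A",
                                  query_options(direction = "incoming"))), 1L)
  expect_equal(nrow(direct_search(g0, "B", "A")), 1L)  # any direction

  res2 <- direct_search(g0, "A", "D",
                        query_options(min_weight_by_source = c(CORD19 = 2)))
  expect_equal(nrow(res2), 0L)  # A->D has weight 1

  expect_error(direct_search(g0, "A", "NOPE"), class = "litkg_missing_node")
})

test_that("fuzzy search ranks exact, prefix, substring and edit-distance tiers", {
  g <- kg_new()
  g <- upsert_node(g, "COVID-19", synonyms = c("2019-nCoV disease"))
  g <- upsert_node(g, "Chloroquine")
  g <- upsert_node(g, "hydroxychloroquine")

  expect_equal(fuzzy_search(g, "covid", fuzzy = TRUE)$label, "COVID-19")

  res <- fuzzy_search(g, "chloroquine", fuzzy = TRUE)
  expect_equal(res$label, c("Chloroquine", "hydroxychloroquine"))
  expect_equal(res$tier, c(1L, 3L))

  expect_equal(fuzzy_search(g, "COVID-19", fuzzy = FALSE)$label, "COVID-19")
  # synonyms participate in non-fuzzy matching too
  expect_equal(fuzzy_search(g, "2019-ncov disease", fuzzy = FALSE)$label,
               "COVID-19")
  # a typo within edit distance 2 of a token
  expect_equal(fuzzy_search(g, "chloroquin", fuzzy = TRUE)$label[1],
               "Chloroquine")
  expect_equal(nrow(fuzzy_search(g, "zzzzzz", fuzzy = TRUE)), 0L)
  expect_error(fuzzy_search(g, ""), class = "litkg_invalid_input")
  expect_equal(nrow(fuzzy_search(g, "c", fuzzy = TRUE, limit = 1)), 1L)
})

test_that("neighborhood expands breadth-first with per-layer thresholds", {
  g0 <- make_g0()
  n1 <- neighborhood(g0, "A", 1)
  expect_setequal(n1$nodes$label, c("A", "B", "D"))
  expect_setequal(paste(n1$edges$head_label, n1$edges$tail_label),
                  c("A B", "A D"))

  n2 <- neighborhood(g0, "A", 2,
                     query_options(min_weight_by_source = c(CORD19 = 2,
                                                            STRING = 700)))
  expect_setequal(n2$nodes$label, c("A", "B", "C"))
  expect_setequal(paste(n2$edges$head_label, n2$edges$tail_label),
                  c("A B", "B C"))

  n0 <- neighborhood(g0, "A", 0)
  expect_equal(n0$nodes$label, "A")
  expect_equal(nrow(n0$edges), 0L)

  expect_error(neighborhood(g0, "A", 3), class = "litkg_invalid_input")
  expect_error(neighborhood(g0, "NOPE", 1), class = "litkg_missing_node")
})

test_that("per-layer overrides apply their own filters at each depth", {
  g0 <- make_g0()
  # layer 1 restricted to TREATS (A->B only); layer 2 to STRING edges
  res <- neighborhood(g0, "A", 2,
                      layer_options = list(
                        query_options(predicates = "TREATS"),
                        query_options(sources = "STRING")))
  expect_setequal(res$nodes$label, c("A", "B", "C"))
})

test_that("path search enumerates simple paths with interior-group filters", {
  g0 <- make_g0()
  p1 <- find_paths(g0, "A", "D", max_len = 3, exclude_direct = TRUE,
                   intermediate_groups = "Genes & Molecular Sequences")
  expect_equal(length(p1$node_labels), 1L)
  expect_equal(p1$node_labels[[1]], c("A", "B", "C", "D"))

  p2 <- find_paths(g0, "A", "D", max_len = 3, exclude_direct = FALSE,
                   intermediate_groups = "Genes & Molecular Sequences")
  expect_equal(p2$node_labels, list(c("A", "D"), c("A", "B", "C", "D")))

  p3 <- find_paths(g0, "E", "A", max_len = 4,
                   options = query_options(direction = "outgoing"))
  expect_equal(nrow(p3), 0L)

  expect_error(find_paths(g0, "A", "D", min_len = 0, max_len = 3),
               class = "litkg_invalid_input")
  expect_error(find_paths(g0, "A", "D", max_len = 5),
               class = "litkg_invalid_input")
})

test_that("pairwise_paths covers every unordered pair", {
  g0 <- make_g0()
  res <- pairwise_paths(g0, c("A", "D", "E"), max_len = 2)
  expect_true(all(c("from", "to") %in% names(res)))
  # pairs in sorted order: A-D, A-E, D-E
  expect_setequal(unique(paste(res$from, res$to)), c("A D", "A E", "D E"))
  expect_error(pairwise_paths(g0, "A"), class = "litkg_invalid_input")
})

test_that("neighborhood and find_paths agree with the naive oracles on random graphs", {
  for (seed in 1:12) {
    g <- random_graph(seed, n_nodes = 10, n_edges = 25)
    opts <- random_options(seed * 31)
    seed_node <- g$nodes$label[1 + seed %% nrow(g$nodes)]
    for (depth in 0:2) {
      got <- neighborhood(g, seed_node, depth, opts)
      want <- oracle_neighborhood(g, seed_node, depth, opts)
      expect_equal(sort(got$nodes$label), want$nodes)
      expect_equal(sort(got$edges$edge_id), want$edge_ids)
    }
    to_node <- g$nodes$label[1 + (seed + 3) %% nrow(g$nodes)]
    if (to_node != seed_node) {
      groups <- if (seed %% 2) "Disorders"
      got_p <- find_paths(g, seed_node, to_node, max_len = 3,
                          exclude_direct = seed %% 3 == 0,
                          intermediate_groups = groups, options = opts)
      want_p <- oracle_paths(g, seed_node, to_node, max_len = 3,
                             exclude_direct = seed %% 3 == 0,
                             intermediate_groups = groups, options = opts)
      expect_equal(path_signatures(got_p), want_p)
    }
  }
})

test_that("tightening any filter never enlarges a result set", {
  g <- random_graph(77, n_nodes = 12, n_edges = 35)
  seed_node <- g$nodes$label[1]
  base <- query_options(min_weight_by_source = c(STRING = 2))
  tight <- query_options(predicates = c("TREATS", "CAUSES"),
                         sources = c("CORD19", "STRING"),
                         min_weight_by_source = c(STRING = 700))
  nb_base <- neighborhood(g, seed_node, 2, base)
  nb_tight <- neighborhood(g, seed_node, 2, tight)
  expect_true(all(nb_tight$nodes$label %in% nb_base$nodes$label))
  expect_true(all(nb_tight$edges$edge_id %in% nb_base$edges$edge_id))

  to_node <- g$nodes$label[5]
  p_base <- path_signatures(find_paths(g, seed_node, to_node, max_len = 3,
                                       options = base))
  p_tight <- path_signatures(find_paths(g, seed_node, to_node, max_len = 3,
                                        options = tight))
  expect_true(all(p_tight %in% p_base))
})

test_that("undirected path search is symmetric under endpoint swap", {
  g <- random_graph(5, n_nodes = 9, n_edges = 20)
  a <- g$nodes$label[1]; b <- g$nodes$label[6]
  fwd <- find_paths(g, a, b, max_len = 3)
  bwd <- find_paths(g, b, a, max_len = 3)
  expect_setequal(
    vapply(fwd$node_labels, paste, character(1), collapse = ">"),
    vapply(lapply(bwd$node_labels, rev), paste, character(1), collapse = ">"))
})
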