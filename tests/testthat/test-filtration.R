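test_that("strip_inferred removes only (INFER)/(SPEC)-suffixed predications", {
  inst <- dplyr::bind_rows(
    make_instances("A", "TREATS(INFER)", "B"),
    make_instances("A", "TREATS(SPEC)", "B"),
    make_instances("A", "TREATS", "B"),
    make_instances("A", "AFFECTS", "C"))
  out <- strip_inferred(inst)
  expect_equal(out$predicate, c("TREATS", "AFFECTS"))
  expect_equal(nrow(strip_inferred(inst[0, ])), 0L)
})

test_that("dictionary normalization rewrites names by longest contained term", {
  dict <- tibble::tibble(
    term = c("2019-ncov disease", "sars-cov-2", "sars-cov-2 infection"),
    subject = c("COVID-19", "SARS-CoV-2", "COVID-19"))

  inst <- make_instances("2019-nCoV disease", "CAUSES", "Pneumonia")
  out <- normalize_instances(inst, dict)
  expect_equal(out$head_name, "COVID-19")
  expect_equal(out$head_cui, "")
  expect_equal(out$tail_name, "Pneumonia")  # no hit: unchanged

  # both "sars-cov-2" and "sars-cov-2 infection" match; the longer wins
  inst2 <- make_instances("Severe SARS-CoV-2 infection", "CAUSES", "Fever")
  out2 <- normalize_instances(inst2, dict)
  expect_equal(out2$head_name, "COVID-19")

  inst3 <- make_instances("SARS-CoV-2 virus", "CAUSES", "Fever")
  expect_equal(normalize_instances(inst3, dict)$head_name, "SARS-CoV-2")

  expect_identical(normalize_instances(inst, dict[0, ]), inst)
})

test_that("ties between equally long terms go to the earliest match position", {
  dict <- tibble::tibble(term = c("alpha", "gamma"), subject = c("S1", "S2"))
  inst <- make_instances("gamma then alpha", "AFFECTS", "X")
  expect_equal(normalize_instances(inst, dict)$head_name, "S2")
})

test_that("filter_instances applies the score filter before the occurrence filter", {
  hcq <- make_instances("HCQ", "TREATS", "COVID-19", n = 3)
  lone <- make_instances("X", "CAUSES", "Y", n = 1)
  out <- filter_instances(dplyr::bind_rows(hcq, lone))
  expect_equal(nrow(out), 3L)
  expect_true(all(out$head_name == "HCQ"))

  # two instances of one triple, one failing the score gate: the survivor is
  # then a singleton and the whole triple is dropped
  pair <- dplyr::bind_rows(
    make_instances("P", "TREATS", "Q", head_score = 790L),
    make_instances("P", "TREATS", "Q"))
  expect_equal(nrow(filter_instances(pair)), 0L)

  all_in <- dplyr::bind_rows(hcq, lone)
  expect_equal(nrow(filter_instances(all_in, min_triple_count = 1)), 4L)
  expect_error(filter_instances(all_in, min_entity_score = -1),
               class = "litkg_invalid_input")
})

test_that("filter_instances matches the brute-force oracle on seeded corpora", {
  for (seed in 1:5) {
    dir <- tempfile("corpus")
    manifest <- generate_corpus(seed, n_documents = 8, n_entities = 15,
                                n_planted_triples = 6,
                                noise = list(n_low_score = 10, n_singleton = 8,
                                             n_inferred = 5, n_variant_triples = 1),
                                dir = dir)
    inst <- read_predications(manifest$files$predications) |>
      strip_inferred() |>
      normalize_instances(read_dictionary(manifest$files$dictionary))
    got <- filter_instances(inst)
    want <- oracle_filter(inst, 800, 2)
    sig <- function(x) paste(x$document_id, x$sentence_id, x$head_name,
                             x$predicate, x$tail_name)
    expect_identical(sig(got), sig(want))
    expect_equal(nrow(got), manifest$expected_survivors_after_filter)
  }
})

test_that("raising either threshold never adds survivors", {
  dir <- tempfile("corpus")
  manifest <- generate_corpus(99, n_documents = 8, n_entities = 15,
                              n_planted_triples = 6, dir = dir)
  inst <- read_predications(manifest$files$predications) |> strip_inferred()
  sig <- function(x) paste(x$document_id, x$sentence_id, x$sentence)
  set.seed(7)
  for (i in 1:25) {
    s <- sort(sample(0:1000, 2)); k <- sort(sample(0:5, 2))
    low <- filter_instances(inst, s[1], k[1])
    high_s <- filter_instances(inst, s[2], k[1])
    high_k <- filter_instances(inst, s[1], k[2])
    expect_true(all(sig(high_s) %in% sig(low)))
    expect_true(all(sig(high_k) %in% sig(low)))
  }
})

test_that("build_graph constructs nodes, weighted edges and one draft per instance", {
  hcq <- make_instances("HCQ", "TREATS", "COVID-19", n = 3)
  built <- build_graph(hcq)
  expect_equal(nrow(built$graph$nodes), 2L)
  expect_equal(nrow(built$graph$edges), 1L)
  expect_equal(built$graph$edges$weight, 3)
  expect_equal(lengths(built$graph$edges$supporting_text_ids), 3L)
  expect_equal(nrow(built$text_drafts), 3L)
  expect_equal(built$graph$edges$source, "CORD19")

  # disjoint triples: one edge each
  inst <- dplyr::bind_rows(make_instances("A", "R1", "B", n = 2),
                           make_instances("C", "R2", "D", n = 2))
  built2 <- build_graph(inst)
  expect_equal(nrow(built2$graph$edges), 2L)

  # an entity seen under two semantic types carries both and both groups
  two <- dplyr::bind_rows(make_instances("A", "R1", "B"),
                          make_instances("A", "R1", "B"))
  two$head_types <- list("gngm", "phsu")
  built3 <- build_graph(two)
  node <- built3$graph$nodes[built3$graph$nodes$label == "A", ]
  expect_setequal(node$semantic_types[[1]], c("gngm", "phsu"))
  expect_setequal(node$semantic_groups[[1]],
                  c("Genes & Molecular Sequences", "Chemicals & Drugs"))
})

test_that("literature edge weights conserve the surviving instance count", {
  for (seed in 1:3) {
    fx <- build_fixture_graph(seed)
    built <- build_graph(fx$instances)
    expect_equal(sum(built$graph$edges$weight), nrow(fx$instances))
  }
})
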