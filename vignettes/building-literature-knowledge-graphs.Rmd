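---
title: "Building and exploring literature-derived knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and exploring literature-derived knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litkg)
```

## The problem and the model

Biomedical literature grows faster than anyone can read it. One way to make
a corpus navigable is to reduce every sentence-level assertion to a
*predication*: a (head entity, relationship, tail entity) triple extracted
by an NLP tool, with a confidence score per entity and the sentence it came
from. litkg turns a table of such predications into an explorable
*knowledge graph* with three record kinds:

* **ITEM** — a concept node, uniquely keyed by its label (a preferred name,
  gene symbol, or dictionary-normalized subject). Concept identifiers
  (CUIs), semantic types, the coarser semantic groups derived from them,
  and surface-form synonyms are *attributes* of the node, not keys: the
  same concept extracted in different contexts may legitimately carry
  several CUIs, and keying on the label is what lets those contexts merge.
* **TEXT** — a supporting sentence, stored once per unique
  (document, sentence) pair and linked from every edge it supports.
* **DOCUMENT** — the source article, with authors, journal, publication
  date and (optionally) the journal impact factor.

Edges are unique per (head, predicate, tail, evidence source). Parallel
edges from different sources are deliberately kept separate, because the
query engine filters per source: a protein-interaction score of 900 from a
curated database and "3 supporting sentences" from the literature are not
commensurable numbers, and collapsing them would destroy the ability to
threshold each on its own scale. For literature edges the weight *is* the
number of supporting texts — provenance doubles as confidence — and this
invariant (`weight == length(supporting_text_ids)`) is enforced by
`kg_validate()` and rechecked after every text deduplication.

Graph **density** is measured on unique directed triples collapsed across
sources, divided by the number of ordered node pairs, with graphs of at
most one node assigned density 0. This is the standard directed
simple-graph definition; we state it explicitly because density is the
quantity by which external-source integration is judged (the before/after
ratio in the integration report).

## The five stages

1. **Ingestion.** Four strict TSV dialects (predications, source rows,
   key-to-CUI maps, normalization dictionaries), each with a versioned
   header line, UTF-8, and literal tabs/newlines forbidden inside fields.
   The dialect is deliberately rigid: extraction tools have idiosyncratic
   output formats, and a documented converter target is more maintainable
   than a lenient parser. Malformed input fails with the offending line
   number; a key mapped to two CUIs and a dictionary term duplicated after
   lower-casing are parse-time errors, not silent last-one-wins choices.

2. **Filtration** (`strip_inferred()`, `normalize_instances()`,
   `filter_instances()`, `build_graph()`). Predications whose predicate
   carries an `(INFER)` or `(SPEC)` suffix are inferred rather than
   asserted and are removed first. Dictionary normalization then maps
   designated surface variants (e.g. dozens of coronavirus-disease
   spellings) onto a single subject label — the longest contained term
   wins, ties break to the earliest match position — and clears the CUI,
   since the subject is a dictionary label rather than a Metathesaurus
   concept. Normalization runs *before* the occurrence filter on purpose:
   pooling variants is precisely what lets their occurrence counts
   aggregate. Finally instances with either entity score below 800 (of
   1000) are dropped, and occurrence counts of unique triples are computed
   *among the score survivors*; triples seen fewer than 2 times go.
   Score-then-count is the only order under which the confidence gate can
   demote a triple below the occurrence threshold, which is the behaviour
   a "keep only high-confidence, recurrent relationships" reading implies.
   Both thresholds are config, not code.

3. **Provenance** (`register_texts()`, `attach_impact_factors()`,
   `supporting_evidence()`). Texts deduplicate on exact
   (document ID, sentence string) identity — no fuzzy sentence matching,
   because near-duplicate abstracts are real and conflating them would
   fabricate evidence counts. The same sentence string in two different
   articles remains two records. Journal impact factors attach by
   case-folded, whitespace-squished exact name match; unmatched journals
   simply stay unset. Dates parse leniently (`YYYY`, `YYYY-MM`,
   `YYYY-MM-DD`) and are stored zero-padded.

4. **Integration** (`integrate_source()`). External relationship tables
   (gene-disease, drug-gene, protein-protein, phenotype annotations) join
   onto the graph by key → CUI → node. Integration *never creates nodes*:
   a relationship between entities the literature never mentioned has no
   anchor in the corpus being explored, and the node-set invariance is
   asserted on every call. A CUI carried by several nodes resolves to the
   lexicographically smallest label; no principled resolution exists
   without corpus frequencies, so we chose the deterministic convention
   and surface every outcome count in the integration report. Per-source
   score gates (e.g. 700 for STRING-style combined scores, 2 for
   DGIdb-style interaction counts) live in the pipeline config.

5. **Export** (`write_bulk_import()`, `read_bulk_import()`). The graph
   serializes to the bulk-import CSV dialect of property-graph databases:
   `label:ID`/`:START_ID`/`:END_ID`/`:TYPE`/`:LABEL` role headers,
   RFC 4180 quoting, `;`-delimited array fields, node IDs equal to node
   labels. Rows are sorted by ID so equal graphs export byte-identically;
   `read_bulk_import()` round-trips exactly, which the test suite uses as
   the definition of the format being complete. A native JSON-lines
   serialization (one file per record kind plus a count manifest) is the
   package's own interchange format.

## The query engine

All searches share one filter vocabulary (`query_options()`): predicate
set, source set, per-source minimum weight, node semantic-group set, and a
traversal direction (`outgoing`, `incoming`, `any`).

* `direct_search()` returns the passing edges between two known labels,
  each paired with its supporting sentences and article metadata.
* `fuzzy_search()` ranks candidate labels by tier — exact, prefix,
  substring, then any label/synonym token within edit distance 2 — with
  ties broken by label length and then lexicographically. Tiered ranking
  keeps exact hits from being swamped by substring noise in
  pharmacological nomenclature (a query for one drug name is usually not a
  request for every derivative containing it).
* `neighborhood()` expands breadth-first to depth ≤ 2, with the seed
  exempt from node filters, and supports per-layer option overrides so a
  two-hop search can apply, say, a database-score gate on the first hop
  and a supporting-text gate on the second. The result contains every
  visited node and every edge that passes its layer's filters, joins two
  visited nodes, and is traversable from an endpoint visited at the
  previous layer.
* `find_paths()` enumerates *simple* paths (no repeated nodes) of bounded
  edge length (≤ 4), optionally excluding the direct edge and constraining
  interior nodes to given semantic groups — the "what mediates the
  relation between these two entities" question. Bounded enumeration
  rather than shortest-path search is intentional: the informative result
  is the set of short mediated routes, not a single geodesic. Cycles are
  excluded because repeated nodes add no mediator information and blow up
  the result set. `pairwise_paths()` runs the same search over all
  unordered pairs of a seed set.

Every operation orders its results deterministically (stated in each
function's documentation), so query output and exports are reproducible
byte-for-byte — a prerequisite for the end-to-end determinism test.

## The synthetic-fixture generator

`generate_corpus()` emulates the statistical shape of a filtered
literature extraction without any linguistic realism: templated sentences
that literally contain the head and tail surfaces at the recorded spans,
planted triples with 2-4 instances and entity scores in 800-1000, and
three noise classes that each pipeline stage must remove (instances with a
sub-threshold score, singleton triples, inferred/speculative
predications). A configurable subset of planted triples appears under
surface variants that only pool after dictionary normalization; about 30%
of repeat instances reuse the previous instance's (document, sentence) to
exercise text deduplication. The manifest records every planted count, so
tests can assert pipeline outputs *exactly* rather than approximately.
`generate_source_tables()` splits rows between mappable and unmappable
(key missing from the CUI map vs CUI absent from every node) with a known
split.

What the generator does *not* model — extraction errors, entity-boundary
mistakes, score miscalibration, duplicated abstracts with textual drift,
polysemous labels — bounds what the tests show: they demonstrate that the
pipeline's mechanics are exact on well-formed input, not that the
downstream science survives a noisy extractor.

Default study-scale conditions used by the acceptance checks: corpora of
roughly 2,000 instances (250 planted triples, 400 low-score, 500
singleton and 350 inferred noise instances over 120 entities and 60
documents), 50 seeded replicates for the filtration oracle, and 100
random graphs of at most 40 nodes/150 edges for the query-engine oracles.

## Numerical and design notes

* Thresholds: entity score ≥ 800, triple occurrence ≥ 2 by default;
  per-source integration gates default to 0 and are set in config (700
  STRING-style, 2 DGIdb-style in the shipped examples).
* Character spans are 0-based half-open; spans must fall inside the
  sentence and not overlap.
* Set-valued attributes are stored sorted and deduplicated, which is what
  makes graph equality and exports order-insensitive.
* `upsert_node()` is idempotent and keeps the first insertion's preferred
  name; semantic groups are always recomputed from the merged type set.
* Degenerate inputs: density of a ≤ 1-node graph is 0; an empty dictionary
  or an empty source list is a no-op; depth-0 neighborhoods return the
  seed alone.
* Corpus-scale statistics of any real deployment (node counts in the
  hundreds of thousands, density shifts from external integration) depend
  on the corpus, the extractor and the licensed vocabularies, and are
  out of scope here; the package asserts the mechanics that produce such
  numbers, not the numbers themselves.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile()
m <- generate_corpus(seed = 1, dir = dir)

instances <- read_predications(m$files$predications) |>
  strip_inferred() |>
  normalize_instances(read_dictionary(m$files$dictionary)) |>
  filter_instances()

built <- build_graph(instances)
g <- built$graph |>
  register_texts(built$text_drafts, read_documents(m$files$documents)) |>
  attach_impact_factors(read_impact_factors(m$files$jif))

glance(g)
src <- generate_source_tables(2, g, dir = tempfile())
g <- integrate_source(g, read_source_table(src$files$source, "STRING"),
                      read_cui_map(src$files$cui_map))
integration_report(g)

neighborhood(g, g$nodes$label[1], depth = 2)
write_bulk_import(g, file.path(dir, "bulk"))
```
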