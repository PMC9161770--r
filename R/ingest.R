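# Strict TSV dialects. Each file starts with a version line ("#litkg/<kind> v1")
# followed by a header row naming the columns in fixed order. Fields are UTF-8;
# literal tabs and newlines inside fields are forbidden (no quoting dialect),
# which keeps the format trivially streamable and diff-able.

tsv_version_line <- function(kind) paste0("#litkg/", kind, " v1")

PREDICATION_COLS <- c(
  "document_id", "sentence_id", "sentence",
  "head_surface", "head_cui", "head_name", "head_types", "head_score",
  "head_start", "head_end",
  "predicate",
  "tail_surface", "tail_cui", "tail_name", "tail_types", "tail_score",
  "tail_start", "tail_end"
)

format_error <- function(path, msg) {
  stop_litkg(paste0(basename(path), ": ", msg), "litkg_format_error")
}

# shared strict reader: checks version line, header, and per-line field counts
read_litkg_tsv <- function(path, kind, columns) {
  if (!file.exists(path))
    stop_litkg(paste0("file not found: ", path), "litkg_invalid_input")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 2L)
    format_error(path, paste0("missing version line or header (expected '",
                              tsv_version_line(kind), "')"))
  if (lines[1L] != tsv_version_line(kind))
    format_error(path, paste0("bad version line '", lines[1L], "' (expected '",
                              tsv_version_line(kind), "')"))
  header <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, columns))
    format_error(path, paste0("header mismatch: expected columns [",
                              paste(columns, collapse = ", "), "], found [",
                              paste(header, collapse = ", "), "]"))
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    out <- as_tibble(stats::setNames(
      replicate(length(columns), character(), simplify = FALSE), columns))
    attr(out, "line_numbers") <- integer()
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty field is dropped by strsplit; pad rows short by one
  fields[nf == length(columns) - 1L] <-
    lapply(fields[nf == length(columns) - 1L], function(f) c(f, ""))
  nf <- lengths(fields)
  bad <- which(nf != length(columns))
  if (length(bad))
    format_error(path, paste0("line ", bad[1L] + 2L, ": expected ",
                              length(columns), " tab-separated fields, found ",
                              nf[bad[1L]]))
  out <- as_tibble(stats::setNames(
    lapply(seq_along(columns), function(i) vapply(fields, `[`, character(1), i)),
    columns))
  attr(out, "line_numbers") <- seq_along(body) + 2L
  out
}

as_int_col <- function(x, path, lines, what, min = NULL, max = NULL) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) & nzchar(x) | (!nzchar(x)))
  if (length(bad))
    format_error(path, paste0("line ", lines[bad[1L]], ": ", what,
                              " is not an integer ('", x[bad[1L]], "')"))
  if (!is.null(min)) {
    bad <- which(v < min | v > max)
    if (length(bad))
      format_error(path, paste0("line ", lines[bad[1L]], ": ", what, " ",
                                v[bad[1L]], " outside [", min, ", ", max, "]"))
  }
  v
}

#' Read a predication file
#'
#' Parses the tab-separated predication dialect: one extracted triple instance
#' per line, with the supporting sentence, per-entity concept IDs (CUIs),
#' semantic-type codes, integer confidence scores in `[0, 1000]`, and 0-based
#' half-open character spans locating head and tail in the sentence. Multiple
#' semantic types within a field are `|`-separated. The predicate may carry an
#' `"(INFER)"` or `"(SPEC)"` suffix marking it as inferred rather than
#' asserted; see [strip_inferred()].
#'
#' @param path path to a predication TSV (version line `#litkg/predications v1`).
#' @return a tibble of triple instances, in file order, with list columns
#'   `head_types`/`tail_types` and integer score and span columns.
#' @export
read_predications <- function(path) {
  raw <- read_litkg_tsv(path, "predications", PREDICATION_COLS)
  lines <- attr(raw, "line_numbers")
  for (side in c("head", "tail")) {
    raw[[paste0(side, "_score")]] <-
      as_int_col(raw[[paste0(side, "_score")]], path, lines,
                 paste0(side, "_score"), min = 0L, max = 1000L)
    raw[[paste0(side, "_start")]] <-
      as_int_col(raw[[paste0(side, "_start")]], path, lines, paste0(side, "_start"))
    raw[[paste0(side, "_end")]] <-
      as_int_col(raw[[paste0(side, "_end")]], path, lines, paste0(side, "_end"))
    bad <- which(raw[[paste0(side, "_start")]] < 0L |
                 raw[[paste0(side, "_start")]] >= raw[[paste0(side, "_end")]] |
                 raw[[paste0(side, "_end")]] > nchar(raw$sentence))
    if (length(bad))
      format_error(path, paste0("line ", lines[bad[1L]], ": ", side,
                                " span outside sentence bounds"))
  }
  bad <- which(!nzchar(raw$predicate))
  if (length(bad))
    format_error(path, paste0("line ", lines[bad[1L]], ": empty predicate"))
  bad <- which(!nzchar(raw$sentence))
  if (length(bad))
    format_error(path, paste0("line ", lines[bad[1L]], ": empty sentence"))
  raw |>
    mutate(
      head_types = strsplit(.data$head_types, "|", fixed = TRUE),
      tail_types = strsplit(.data$tail_types, "|", fixed = TRUE)
    )
}

#' Read an external relationship table
#'
#' Rows carry two source-native entity keys, a relation type and a numeric
#' per-row score (e.g. a STRING combined score or a DGIdb interaction score).
#'
#' @param path path to a source TSV (version line `#litkg/source v1`; columns
#'   `key_a`, `key_b`, `relation`, `score`).
#' @param source_name name recorded on every row (e.g. `"STRING"`).
#' @return a tibble with columns `source`, `key_a`, `key_b`, `relation`,
#'   `score`.
#' @export
read_source_table <- function(path, source_name) {
  raw <- read_litkg_tsv(path, "source", c("key_a", "key_b", "relation", "score"))
  lines <- attr(raw, "line_numbers")
  bad <- which(!nzchar(raw$key_a) | !nzchar(raw$key_b))
  if (length(bad))
    format_error(path, paste0("line ", lines[bad[1L]], ": empty entity key"))
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(score))
  if (length(bad))
    format_error(path, paste0("line ", lines[bad[1L]], ": score '",
                              raw$score[bad[1L]], "' is not a number"))
  tibble(source = source_name, key_a = raw$key_a, key_b = raw$key_b,
         relation = raw$relation, score = score)
}

#' Read a key-to-CUI mapping table
#'
#' Maps source-native entity keys (HGNC IDs, Disease Ontology IDs, ...) to
#' UMLS-style Concept Unique Identifiers. A key listed twice with the same CUI
#' is deduplicated; a key mapped to two different CUIs is a format error.
#'
#' @param path path to a CUI-map TSV (version line `#litkg/cuimap v1`; columns
#'   `key`, `cui`).
#' @return a tibble with columns `key`, `cui` (one row per key).
#' @export
read_cui_map <- function(path) {
  raw <- read_litkg_tsv(path, "cuimap", c("key", "cui"))
  lines <- attr(raw, "line_numbers")
  bad <- which(!nzchar(raw$key) | !nzchar(raw$cui))
  if (length(bad))
    format_error(path, paste0("line ", lines[bad[1L]], ": empty key or CUI"))
  out <- distinct(tibble(key = raw$key, cui = raw$cui))
  dup <- out$key[duplicated(out$key)]
  if (length(dup))
    format_error(path, paste0("key '", dup[1L],
                              "' is mapped to more than one CUI"))
  out
}

#' Read a term-normalization dictionary
#'
#' Maps lower-cased surface terms onto a normalized subject label (e.g. many
#' coronavirus-disease surface variants onto one disease label). Terms are
#' lower-cased on read; two terms identical after lower-casing are a format
#' error.
#'
#' @param path path to a dictionary TSV (version line `#litkg/dictionary v1`;
#'   columns `term`, `subject`).
#' @return a tibble with columns `term` (lower-cased), `subject`.
#' @export
read_dictionary <- function(path) {
  raw <- read_litkg_tsv(path, "dictionary", c("term", "subject"))
  lines <- attr(raw, "line_numbers")
  bad <- which(!nzchar(raw$term) | !nzchar(raw$subject))
  if (length(bad))
    format_error(path, paste0("line ", lines[bad[1L]], ": empty term or subject"))
  out <- tibble(term = tolower(raw$term), subject = raw$subject)
  dup <- out$term[duplicated(out$term)]
  if (length(dup))
    format_error(path, paste0("term '", dup[1L],
                              "' duplicated after lower-casing"))
  out
}

#' Read an article metadata table
#'
#' @param path path to a document TSV (version line `#litkg/documents v1`;
#'   columns `document_id`, `title`, `authors` (`|`-separated), `journal`,
#'   `publish_date`).
#' @return a tibble with one row per article; `authors` is a list column.
#' @export
read_documents <- function(path) {
  raw <- read_litkg_tsv(path, "documents",
                        c("document_id", "title", "authors", "journal",
                          "publish_date"))
  lines <- attr(raw, "line_numbers")
  bad <- which(!nzchar(raw$document_id))
  if (length(bad))
    format_error(path, paste0("line ", lines[bad[1L]], ": empty document_id"))
  dup <- raw$document_id[duplicated(raw$document_id)]
  if (length(dup))
    format_error(path, paste0("duplicate document_id '", dup[1L], "'"))
  raw |>
    mutate(authors = lapply(strsplit(.data$authors, "|", fixed = TRUE),
                            function(a) a[nzchar(a)])) |>
    select("document_id", "title", "authors", "journal", "publish_date")
}

#' Read a journal impact-factor table
#'
#' @param path path to an impact-factor TSV (version line `#litkg/jif v1`;
#'   columns `journal`, `impact_factor`).
#' @return a tibble with columns `journal`, `impact_factor` (numeric).
#' @export
read_impact_factors <- function(path) {
  raw <- read_litkg_tsv(path, "jif", c("journal", "impact_factor"))
  lines <- attr(raw, "line_numbers")
  jif <- suppressWarnings(as.numeric(raw$impact_factor))
  bad <- which(is.na(jif))
  if (length(bad))
    format_error(path, paste0("line ", lines[bad[1L]],
                              ": impact_factor is not a number"))
  tibble(journal = raw$journal, impact_factor = jif)
}

# ---- writers (fixture generation, CLI round trips) -------------------------

check_no_tabs <- function(x, what) {
  if (any(grepl("[\t\n\r]", x)))
    stop_litkg(paste0(what, " must not contain tabs or newlines"),
               "litkg_invalid_input")
  x
}

write_litkg_tsv <- function(rows, path, kind, columns) {
  rows <- lapply(rows, function(col) check_no_tabs(as.character(col), kind))
  body <- do.call(paste, c(rows, sep = "\t"))
  writeLines(c(tsv_version_line(kind), paste(columns, collapse = "\t"), body),
             path, useBytes = TRUE)
  invisible(path)
}

#' Write triple instances in the predication dialect
#'
#' @param instances tibble as returned by [read_predications()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_predications <- function(instances, path) {
  x <- instances |>
    mutate(head_types = vapply(.data$head_types, paste, character(1), collapse = "|"),
           tail_types = vapply(.data$tail_types, paste, character(1), collapse = "|"))
  write_litkg_tsv(as.list(x[PREDICATION_COLS]), path, "predications",
                  PREDICATION_COLS)
}

#' @rdname write_predications
#' @param documents tibble as returned by [read_documents()].
#' @export
write_documents <- function(documents, path) {
  x <- documents |>
    mutate(authors = vapply(.data$authors, paste, character(1), collapse = "|"))
  write_litkg_tsv(as.list(x[c("document_id", "title", "authors", "journal",
                              "publish_date")]),
                  path, "documents",
                  c("document_id", "title", "authors", "journal", "publish_date"))
}

#' @rdname write_predications
#' @param rows tibble with columns `key_a`, `key_b`, `relation`, `score`.
#' @export
write_source_table <- function(rows, path) {
  write_litkg_tsv(as.list(rows[c("key_a", "key_b", "relation", "score")]),
                  path, "source", c("key_a", "key_b", "relation", "score"))
}

#' @rdname write_predications
#' @param cui_map tibble with columns `key`, `cui`.
#' @export
write_cui_map <- function(cui_map, path) {
  write_litkg_tsv(as.list(cui_map[c("key", "cui")]), path, "cuimap",
                  c("key", "cui"))
}

#' @rdname write_predications
#' @param dictionary tibble with columns `term`, `subject`.
#' @export
write_dictionary <- function(dictionary, path) {
  write_litkg_tsv(as.list(dictionary[c("term", "subject")]), path, "dictionary",
                  c("term", "subject"))
}

#' @rdname write_predications
#' @param jif tibble with columns `journal`, `impact_factor`.
#' @export
write_impact_factors <- function(jif, path) {
  write_litkg_tsv(as.list(jif[c("journal", "impact_factor")]), path, "jif",
                  c("journal", "impact_factor"))
}
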