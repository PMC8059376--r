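#' Controlled vocabularies for the fine-mapping catalog
#'
#' The catalog covers 15 autoimmune diseases; coding consequence classes
#' follow VEP/SIFT/PolyPhen-style groupings; prioritization method classes
#' distinguish statistical, functional-experimental and integrative
#' fine-mapping; the seven evidence categories are the gene-prioritization
#' strategy families used by the confidence-scoring framework.
#'
#' @return A character vector of vocabulary codes.
#' @export
disease_codes <- function() {
  c("CD", "UC", "IBD", "RA", "JIA", "PSO", "T1D", "MS", "SLE", "SS",
    "VIT", "BD", "PSA", "GD", "AS")
}

#' @rdname disease_codes
#' @export
coding_classes <- function() {
  c("pLOF", "missense_damaging", "missense_benign", "noncoding", "unknown")
}

#' @rdname disease_codes
#' @export
method_classes <- function() {
  c("statistical", "functional", "integrative")
}

#' @rdname disease_codes
#' @export
evidence_categories <- function() {
  c("pLOF_missense_damaging", "gene_based_association",
    "molecular_qtl_colocalization", "chromatin_interaction",
    "experimental_followup", "network_coexpression", "integrative_algorithm")
}

# canonical column order per table kind
catalog_schema <- function(kind) {
  switch(kind,
    signals = c("locus_id", "chrom", "disease", "signal_rank", "variant_id",
                "risk_allele_freq", "odds_ratio", "coding_class", "study_id"),
    variants = c("locus_id", "chrom", "disease", "signal_rank", "method_class",
                 "variant_id", "coding_class", "direction_of_effect",
                 "study_id"),
    genes = c("locus_id", "chrom", "disease", "gene", "category", "study_id"),
    abstracts = c("abstract_id", "pub_date", "text"),
    abort(paste0("unknown catalog kind: ", kind))
  )
}

catalog_kinds <- function() c("signals", "variants", "genes", "abstracts")

# strtod-based numeric conversion; unparseable fields are surfaced with
# their row numbers rather than silently dropped
parse_numeric_cols <- function(tbl, cols) {
  for (col in cols) {
    parsed <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(!is.na(tbl[[col]]) & is.na(parsed))
    if (length(bad) > 0) {
      abort(c(paste0("unparseable numeric field '", col, "'"),
              paste0("row ", bad, ": '", tbl[[col]][bad], "'")))
    }
    tbl[[col]] <- parsed
  }
  tbl
}

check_kind <- function(kind) {
  arg_match0(kind, catalog_kinds())
}

catalog_col_types <- function(kind) {
  switch(kind,
    # numeric fields are read as character and converted with strtod so
    # parsing is correctly rounded and round-trips are byte-stable
    signals = readr::cols(
      locus_id = readr::col_character(), chrom = readr::col_character(),
      disease = readr::col_character(), signal_rank = readr::col_integer(),
      variant_id = readr::col_character(),
      risk_allele_freq = readr::col_character(),
      odds_ratio = readr::col_character(),
      coding_class = readr::col_character(),
      study_id = readr::col_character()),
    variants = readr::cols(
      locus_id = readr::col_character(), chrom = readr::col_character(),
      disease = readr::col_character(), signal_rank = readr::col_integer(),
      method_class = readr::col_character(),
      variant_id = readr::col_character(),
      coding_class = readr::col_character(),
      direction_of_effect = readr::col_character(),
      study_id = readr::col_character()),
    genes = readr::cols(
      locus_id = readr::col_character(), chrom = readr::col_character(),
      disease = readr::col_character(), gene = readr::col_character(),
      category = readr::col_character(), study_id = readr::col_character()),
    abstracts = readr::cols(
      abstract_id = readr::col_character(), pub_date = readr::col_date(),
      text = readr::col_character())
  )
}

#' Read one catalog table
#'
#' Parses a tab-delimited catalog table (`"."` for missing, header row
#' required) into a validated tibble. Abstract records are alternatively
#' accepted as one-JSON-object-per-line files (`.json`/`.jsonl`).
#'
#' @param path Path to a TSV (or JSON-lines, abstracts only) file.
#' @param kind One of `"signals"`, `"variants"`, `"genes"`, `"abstracts"`.
#' @param categories Evidence-category vocabulary used to validate gene
#'   records (default [evidence_categories()]).
#' @return A tibble with the canonical columns for `kind` and attribute
#'   `catalog_kind` set.
#' @export
read_catalog <- function(path, kind, categories = evidence_categories()) {
  kind <- check_kind(kind)
  if (!file.exists(path)) {
    abort(paste0("catalog file does not exist: ", path))
  }
  if (kind == "abstracts" && grepl("\\.jsonl?$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    tbl <- purrr::map_dfr(lines, function(l) {
      as_tibble(jsonlite::fromJSON(l))
    })
    tbl$pub_date <- as.Date(tbl$pub_date)
  } else {
    header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
    spec <- catalog_col_types(kind)
    spec$cols <- spec$cols[intersect(names(spec$cols), header)]
    tbl <- readr::read_tsv(path, col_types = spec, na = ".",
                           progress = FALSE)
    probs <- readr::problems(tbl)
    if (nrow(probs) > 0) {
      bad <- paste0("row ", probs$row, ": expected ", probs$expected,
                    ", got '", probs$actual, "'")
      abort(c("unparseable fields in catalog file", bad))
    }
  }
  missing_cols <- setdiff(catalog_schema(kind), names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- tbl[, catalog_schema(kind)]
  if (kind == "signals") {
    tbl <- parse_numeric_cols(tbl, c("risk_allele_freq", "odds_ratio"))
  }
  report <- validate_catalog(tbl, kind, categories = categories)
  if (nrow(report) > 0) {
    msgs <- paste0("row ", report$row, " [", report$column, "]: ",
                   report$problem)
    abort(c("catalog validation failed", head(msgs, 20)))
  }
  attr(tbl, "catalog_kind") <- kind
  tbl
}

#' Write one catalog table
#'
#' Serialises a catalog tibble as TSV with the canonical column order and
#' `"."` for missing values. Writing then re-reading then re-writing an
#' unmodified table is byte-identical.
#'
#' @param records A catalog tibble.
#' @param path Output file path.
#' @param kind Table kind; defaults to the tibble's `catalog_kind` attribute.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(records, path, kind = NULL) {
  kind <- kind %||% attr(records, "catalog_kind")
  if (is.null(kind)) {
    abort("`kind` not given and records carry no catalog_kind attribute")
  }
  kind <- check_kind(kind)
  missing_cols <- setdiff(catalog_schema(kind), names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records are not a ", kind, " table; missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  readr::write_tsv(records[, catalog_schema(kind)], path, na = ".",
                   progress = FALSE)
  invisible(path)
}

#' Validate a catalog table
#'
#' Checks per-row invariants (ranges, controlled vocabularies, non-empty
#' identifiers) and cross-record duplicates. Reporting only: never throws for
#' invalid content, and the report is empty iff all invariants hold.
#'
#' @inheritParams write_catalog
#' @inheritParams read_catalog
#' @return A tibble with columns `row`, `column`, `problem` (zero rows when
#'   the table is valid).
#' @export
validate_catalog <- function(records, kind = NULL,
                             categories = evidence_categories()) {
  kind <- kind %||% attr(records, "catalog_kind")
  if (is.null(kind)) {
    abort("`kind` not given and records carry no catalog_kind attribute")
  }
  kind <- check_kind(kind)
  findings <- list()
  note <- function(rows, column, problem) {
    if (length(rows) > 0) {
      findings[[length(findings) + 1]] <<-
        tibble(row = as.integer(rows), column = column, problem = problem)
    }
  }
  bad_vocab <- function(x, vocab) which(!is.na(x) & !(x %in% vocab))

  if (kind == "signals") {
    note(which(is.na(records$locus_id) | records$locus_id == ""),
         "locus_id", "locus_id must be non-empty")
    note(which(!is.na(records$risk_allele_freq) &
               (records$risk_allele_freq < 0 | records$risk_allele_freq > 1)),
         "risk_allele_freq", "risk_allele_freq must lie in [0, 1]")
    note(which(!is.na(records$odds_ratio) & records$odds_ratio <= 0),
         "odds_ratio", "odds_ratio must be > 0")
    note(which(!is.na(records$signal_rank) & records$signal_rank < 1),
         "signal_rank", "signal_rank must be >= 1")
    note(bad_vocab(records$coding_class, coding_classes()),
         "coding_class", "coding_class not in vocabulary")
    key <- paste(records$locus_id, records$disease, records$signal_rank,
                 records$study_id, sep = "\r")
    note(which(duplicated(key)), "signal_rank",
         "duplicate (locus, disease, signal_rank, study_id)")
  } else if (kind == "variants") {
    note(which(is.na(records$variant_id) | records$variant_id == ""),
         "variant_id", "variant_id must be non-empty")
    note(bad_vocab(records$method_class, method_classes()),
         "method_class", "method_class not in vocabulary")
    note(bad_vocab(records$coding_class, coding_classes()),
         "coding_class", "coding_class not in vocabulary")
    note(bad_vocab(records$direction_of_effect, c("risk", "protective")),
         "direction_of_effect", "direction must be risk/protective/missing")
  } else if (kind == "genes") {
    note(which(is.na(records$gene) | records$gene == ""),
         "gene", "gene must be non-empty")
    note(bad_vocab(records$category, categories),
         "category", "category not in the configured vocabulary")
  } else if (kind == "abstracts") {
    note(which(is.na(records$text) | records$text == ""),
         "text", "abstract text must be non-empty")
  }
  if (length(findings) == 0) {
    return(tibble(row = integer(), column = character(),
                  problem = character()))
  }
  arrange(bind_rows(findings), row)
}

#' Orient signal records to the risk allele
#'
#' Some sources report the protective allele (odds ratio below 1). When
#' `flip = TRUE`, rows with `odds_ratio < 1` are re-oriented: the odds ratio
#' is inverted and the reported allele frequency replaced by its complement,
#' so every row describes the risk allele.
#'
#' @param signals A signals catalog tibble.
#' @param flip Re-orient rows with OR below 1? Default `TRUE`.
#' @return The signals tibble, re-oriented.
#' @export
normalize_risk_orientation <- function(signals, flip = TRUE) {
  if (!flip) return(signals)
  signals %>%
    mutate(
      risk_allele_freq = if_else(.data$odds_ratio < 1,
                                 1 - .data$risk_allele_freq,
                                 .data$risk_allele_freq),
      odds_ratio = if_else(.data$odds_ratio < 1,
                           1 / .data$odds_ratio, .data$odds_ratio))
}
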