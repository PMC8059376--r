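#' Default autoimmune-disease phrase list for abstract screening
#'
#' Disease labels covering the autoimmune diseases represented in the
#' catalog, including common spelling variants. Fully overridable through
#' [screen_config()]: ontology snapshots differ between releases, so the
#' packaged list is a starting point, not a frozen standard.
#'
#' @return Character vector of disease phrases.
#' @export
default_disease_terms <- function() {
  c("Crohn disease", "Crohn's disease", "ulcerative colitis",
    "inflammatory bowel disease", "rheumatoid arthritis",
    "juvenile idiopathic arthritis", "psoriasis", "psoriatic arthritis",
    "type 1 diabetes", "multiple sclerosis", "systemic lupus erythematosus",
    "lupus", "systemic sclerosis", "vitiligo", "Behcet disease",
    "Behcet's disease", "Graves disease", "Graves' disease",
    "ankylosing spondylitis", "celiac disease", "autoimmune")
}

#' Configuration for the two-stage abstract screen
#'
#' Stage 1 retains abstracts whose text contains at least one GWAS term AND
#' at least one mechanism/fine-mapping term; stage 2 additionally requires at
#' least one autoimmune-disease term. A date window is applied before either
#' stage.
#'
#' @param gwas_terms Phrases identifying GWAS abstracts.
#' @param mechanism_terms Words identifying fine-mapping/mechanism abstracts.
#'   Matching is on exact word tokens, so singular and plural forms are
#'   distinct entries.
#' @param disease_terms Autoimmune-disease phrases.
#' @param date_window Length-2 vector of dates (start, end), inclusive.
#' @param match_title Also match terms in a `title` column when present?
#'   Off by default: the screen is defined over abstract text.
#' @return A `screen_config` list.
#' @export
screen_config <- function(gwas_terms = c("GWAS", "genome-wide association"),
                          mechanism_terms = c("functional", "causal",
                                              "mechanisms", "causative",
                                              "mechanism", "mechanistic"),
                          disease_terms = default_disease_terms(),
                          date_window = as.Date(c("2005-01-01",
                                                  "2020-01-31")),
                          match_title = FALSE) {
  stopifnot(length(gwas_terms) > 0, length(mechanism_terms) > 0,
            length(disease_terms) > 0, length(date_window) == 2)
  date_window <- as.Date(date_window)
  if (date_window[1] > date_window[2]) {
    abort("date_window start must not be after end")
  }
  structure(
    list(gwas_terms = gwas_terms, mechanism_terms = mechanism_terms,
         disease_terms = disease_terms, date_window = date_window,
         match_title = match_title),
    class = "screen_config")
}

# lower-case word tokens; hyphenated compounds ("genome-wide") stay one token
screen_tokens <- function(text) {
  stringr::str_extract_all(tolower(text), "[a-z0-9]+(?:-[a-z0-9]+)*")
}

# which of `phrases` occur in `text` as exact token sequences
match_phrases <- function(text, phrases) {
  toks <- screen_tokens(text)
  padded <- vapply(toks, function(tk) {
    paste0(" ", paste(tk, collapse = " "), " ")
  }, character(1))
  needles <- vapply(screen_tokens(phrases), function(tk) {
    paste0(" ", paste(tk, collapse = " "), " ")
  }, character(1))
  lapply(padded, function(p) phrases[stringr::str_detect(p,
                                                         stringr::fixed(needles))])
}

#' Screen abstracts through the two-stage text-mining funnel
#'
#' @param records Abstracts tibble with columns `abstract_id`, `pub_date`,
#'   `text` (see [read_catalog()]).
#' @param config A [screen_config()].
#' @return A `screen_result` tibble with one row per input record: the date
#'   window flag, the matched terms of each class (collapsed with `";"`,
#'   `NA` when none), and logical `stage1`/`stage2` retention flags.
#'   [glance()] returns the funnel counts.
#' @examples
#' abs <- tibble::tibble(
#'   abstract_id = "a1", pub_date = as.Date("2015-06-01"),
#'   text = "A GWAS identified a causal variant in Crohn disease.")
#' screen_abstracts(abs, screen_config())
#' @export
screen_abstracts <- function(records, config = screen_config()) {
  if (nrow(records) == 0) {
    res <- tibble(abstract_id = character(), pub_date = as.Date(character()),
                  in_window = logical(), gwas_matched = character(),
                  mechanism_matched = character(), disease_matched = character(),
                  stage1 = logical(), stage2 = logical())
    return(new_screen_result(res))
  }
  text <- records$text
  if (isTRUE(config$match_title) && "title" %in% names(records)) {
    text <- paste(records$title, text)
  }
  in_window <- records$pub_date >= config$date_window[1] &
    records$pub_date <= config$date_window[2]
  collapse <- function(x) if (length(x) == 0) NA_character_ else
    paste(x, collapse = ";")
  gw <- match_phrases(text, config$gwas_terms)
  me <- match_phrases(text, config$mechanism_terms)
  di <- match_phrases(text, config$disease_terms)
  res <- tibble(
    abstract_id = records$abstract_id,
    pub_date = records$pub_date,
    in_window = in_window,
    gwas_matched = vapply(gw, collapse, character(1)),
    mechanism_matched = vapply(me, collapse, character(1)),
    disease_matched = vapply(di, collapse, character(1)))
  res$stage1 <- res$in_window & lengths(gw) > 0 & lengths(me) > 0
  res$stage2 <- res$stage1 & lengths(di) > 0
  new_screen_result(res)
}

new_screen_result <- function(tbl) {
  class(tbl) <- c("screen_result", class(tbl))
  tbl
}

#' @export
glance.screen_result <- function(x, ...) {
  tibble(n_input = nrow(x), n_window = sum(x$in_window),
         n_stage1 = sum(x$stage1), n_stage2 = sum(x$stage2))
}

#' @export
tidy.screen_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @describeIn screen_abstracts Funnel bar chart of the staged counts.
#' @param x A `screen_result`.
#' @param ... Unused.
#' @export
autoplot.screen_result <- function(x, ...) {
  counts <- glance(x)
  df <- tibble(
    stage = factor(c("input", "date window", "GWAS + mechanism",
                     "+ autoimmune disease"),
                   levels = c("input", "date window", "GWAS + mechanism",
                              "+ autoimmune disease")),
    n = c(counts$n_input, counts$n_window, counts$n_stage1, counts$n_stage2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "abstracts retained",
                  title = "Two-stage abstract screening funnel") +
    ggplot2::theme_minimal()
}
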