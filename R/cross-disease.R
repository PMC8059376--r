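# parse a base-pair position out of chrom:pos:ref:alt IDs; NA for rsIDs
variant_position <- function(variant_id) {
  parts <- stringr::str_split(variant_id, stringr::fixed(":"))
  vapply(parts, function(p) {
    if (length(p) >= 2) suppressWarnings(as.numeric(p[2])) else NA_real_
  }, numeric(1))
}

#' Disease pairs sharing fine-mapped loci
#'
#' Enumerates unordered disease pairs that have at least one locus
#' fine-mapped for both diseases, with the shared loci listed per pair.
#'
#' @param variants A variants catalog tibble.
#' @return A tibble with columns `disease_a`, `disease_b` (sorted so
#'   `disease_a < disease_b`), `locus_id`; one row per shared locus per
#'   pair.
#' @export
shared_locus_pairs <- function(variants) {
  empty <- tibble(disease_a = character(), disease_b = character(),
                  locus_id = character())
  if (nrow(variants) == 0) return(empty)
  per_locus <- variants %>%
    distinct(.data$locus_id, .data$disease) %>%
    group_by(.data$locus_id) %>%
    summarise(diseases = list(sort(unique(.data$disease))),
              .groups = "drop") %>%
    filter(lengths(.data$diseases) >= 2)
  if (nrow(per_locus) == 0) return(empty)
  purrr::map_dfr(seq_len(nrow(per_locus)), function(i) {
    d <- per_locus$diseases[[i]]
    prs <- utils::combn(d, 2)
    tibble(disease_a = prs[1, ], disease_b = prs[2, ],
           locus_id = per_locus$locus_id[i])
  }) %>%
    arrange(.data$disease_a, .data$disease_b, .data$locus_id)
}

# per (pair, locus) comparison rows: the two prioritized-variant sets and
# their intersection
pair_locus_comparisons <- function(variants) {
  pairs <- shared_locus_pairs(variants)
  if (nrow(pairs) == 0) {
    return(mutate(pairs, variants_a = list(), variants_b = list(),
                  shared = list(), overlap = logical()))
  }
  sets <- variants %>%
    group_by(.data$locus_id, .data$disease) %>%
    summarise(vars = list(unique(.data$variant_id)), .groups = "drop")
  pairs %>%
    left_join(rename(sets, variants_a = "vars"),
              by = c(locus_id = "locus_id", disease_a = "disease")) %>%
    left_join(rename(sets, variants_b = "vars"),
              by = c(locus_id = "locus_id", disease_b = "disease")) %>%
    mutate(shared = purrr::map2(.data$variants_a, .data$variants_b,
                                intersect),
           overlap = lengths(.data$shared) > 0)
}

#' Prioritized-variant overlap between diseases at shared loci
#'
#' For every disease pair and every locus fine-mapped for both, a locus
#' "overlaps" when the two prioritized-variant sets intersect (partial
#' overlap counts). Reports per-pair counts plus two global fractions: the
#' fraction of disease pairs with at least one overlapping locus, and the
#' fraction of individual (pair, locus) comparisons that overlap.
#'
#' @param variants A variants catalog tibble.
#' @return An `overlap_summary` object. `tidy()` gives the per-pair counts
#'   (`n_shared_loci`, `n_loci_with_overlap`, `n_loci_without`), `glance()`
#'   the global fractions.
#' @export
variant_overlap <- function(variants) {
  comp <- pair_locus_comparisons(variants)
  per_pair <- comp %>%
    group_by(.data$disease_a, .data$disease_b) %>%
    summarise(n_shared_loci = n(),
              n_loci_with_overlap = sum(.data$overlap),
              n_loci_without = sum(!.data$overlap),
              .groups = "drop")
  structure(
    list(per_pair = per_pair, comparisons = comp,
         pair_fraction = if (nrow(per_pair) > 0) {
           mean(per_pair$n_loci_with_overlap > 0)
         } else NA_real_,
         locus_fraction = if (nrow(comp) > 0) mean(comp$overlap)
         else NA_real_),
    class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary> ", nrow(x$per_pair), " disease pair(s); ",
      "pair-level overlap ", formatC(100 * x$pair_fraction, digits = 1,
                                     format = "f"),
      "%, locus-level ", formatC(100 * x$locus_fraction, digits = 1,
                                 format = "f"), "%\n", sep = "")
  invisible(x)
}

#' @export
tidy.overlap_summary <- function(x, ...) {
  x$per_pair
}

#' @export
glance.overlap_summary <- function(x, ...) {
  tibble(n_pairs = nrow(x$per_pair),
         n_comparisons = nrow(x$comparisons),
         pair_overlap_fraction = x$pair_fraction,
         locus_overlap_fraction = x$locus_fraction)
}

#' Direction-of-effect concordance at shared prioritized variants
#'
#' For each disease pair and shared locus, one representative shared variant
#' is selected per independent association signal (the lowest genomic
#' position, deterministically; variant-ID order breaks remaining ties).
#' A representative is concordant when the same allele is the risk allele
#' for both diseases. Variants lacking a direction for either disease are
#' tallied as unassessed, never guessed.
#'
#' @param variants A variants catalog tibble with `direction_of_effect`
#'   filled for shared variants.
#' @return A `concordance_summary` object. `tidy()` gives per-pair
#'   concordant/discordant counts; `glance()` the global percent concordant
#'   and the unassessed tally.
#' @export
direction_concordance <- function(variants) {
  comp <- pair_locus_comparisons(variants)
  dir_tbl <- variants %>%
    group_by(.data$locus_id, .data$disease, .data$variant_id) %>%
    summarise(direction = first(.data$direction_of_effect[
      !is.na(.data$direction_of_effect)]) %||% NA_character_,
      signal_rank = min(.data$signal_rank), .groups = "drop")
  rows <- purrr::map_dfr(seq_len(nrow(comp)), function(i) {
    shared <- comp$shared[[i]]
    if (length(shared) == 0) return(NULL)
    tibble(disease_a = comp$disease_a[i], disease_b = comp$disease_b[i],
           locus_id = comp$locus_id[i], variant_id = shared)
  })
  if (nrow(rows) == 0) {
    return(structure(list(
      per_pair = tibble(disease_a = character(), disease_b = character(),
                        n_concordant = integer(), n_discordant = integer()),
      selected = rows, pct_concordant = NA_real_, n_unassessed = 0L),
      class = "concordance_summary"))
  }
  rows <- rows %>%
    left_join(rename(dir_tbl, direction_a = "direction",
                     rank_a = "signal_rank"),
              by = c(locus_id = "locus_id", disease_a = "disease",
                     variant_id = "variant_id")) %>%
    left_join(select_direction_b(dir_tbl),
              by = c(locus_id = "locus_id", disease_b = "disease",
                     variant_id = "variant_id")) %>%
    mutate(position = variant_position(.data$variant_id))
  # one representative per (pair, locus, independent signal)
  selected <- rows %>%
    arrange(.data$position, .data$variant_id) %>%
    group_by(.data$disease_a, .data$disease_b, .data$locus_id,
             .data$rank_a) %>%
    slice(1) %>%
    ungroup() %>%
    mutate(assessed = !is.na(.data$direction_a) & !is.na(.data$direction_b),
           concordant = .data$direction_a == .data$direction_b)
  assessed <- filter(selected, .data$assessed)
  per_pair <- assessed %>%
    group_by(.data$disease_a, .data$disease_b) %>%
    summarise(n_concordant = sum(.data$concordant),
              n_discordant = sum(!.data$concordant), .groups = "drop")
  structure(
    list(per_pair = per_pair, selected = selected,
         pct_concordant = if (nrow(assessed) > 0) {
           100 * mean(assessed$concordant)
         } else NA_real_,
         n_unassessed = sum(!selected$assessed)),
    class = "concordance_summary")
}

select_direction_b <- function(dir_tbl) {
  rename(dir_tbl[, c("locus_id", "disease", "variant_id", "direction")],
         direction_b = "direction")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("<concordance_summary> ", nrow(x$per_pair), " disease pair(s); ",
      formatC(x$pct_concordant, digits = 1, format = "f"),
      "% concordant (", x$n_unassessed, " unassessed)\n", sep = "")
  invisible(x)
}

#' @export
tidy.concordance_summary <- function(x, ...) {
  x$per_pair
}

#' @export
glance.concordance_summary <- function(x, ...) {
  tibble(n_pairs = nrow(x$per_pair),
         n_assessed = sum(x$per_pair$n_concordant) +
           sum(x$per_pair$n_discordant),
         n_unassessed = x$n_unassessed,
         pct_concordant = x$pct_concordant)
}
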