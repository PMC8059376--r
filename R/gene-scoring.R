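#' Evidence-category weights for gene confidence scoring
#'
#' The seven gene-prioritization categories are weighted to reflect the
#' consensus of confidence in each class of evidence: direct coding evidence
#' (pLOF/damaging missense among prioritized variants) and gene-based rare
#' variant association outrank every other category. Defaults give those
#' two a weight of 2 and all others 1; any positive weights respecting that
#' ordering are accepted.
#'
#' @param w Named positive numeric vector covering every category in
#'   `categories`.
#' @param categories The category vocabulary (default
#'   [evidence_categories()]).
#' @return A named numeric vector of class `evidence_weights`.
#' @export
evidence_weights <- function(w = NULL, categories = evidence_categories()) {
  if (is.null(w)) {
    w <- setNames(rep(1, length(categories)), categories)
    w[c("pLOF_missense_damaging", "gene_based_association")] <- 2
  }
  if (!all(categories %in% names(w))) {
    abort("weights must name every evidence category")
  }
  w <- w[categories]
  if (any(w <= 0)) abort("all weights must be positive")
  top <- intersect(c("pLOF_missense_damaging", "gene_based_association"),
                   categories)
  if (length(top) > 0 && any(w[top] < max(w))) {
    abort("pLOF/missense-damaging and gene-based association must carry the largest weights")
  }
  structure(w, class = c("evidence_weights", "numeric"))
}

#' Weighted total evidence score per gene and locus context
#'
#' For each gene in each locus context, `E_g = sum_i w_i * e_i`, where
#' `e_i` is 1 when at least one record supports the gene in evidence
#' category `i` (duplicate records within a category never double-count).
#' In `per_disease` mode the context is the (locus, disease) combination;
#' in `disease_agnostic` mode evidence from every disease with a signal at
#' the locus is pooled and the context is the locus alone (`disease =
#' "ALL"`).
#'
#' @param records A genes catalog tibble.
#' @param weights An [evidence_weights()] vector.
#' @param mode `"per_disease"` or `"disease_agnostic"`.
#' @return A tibble with columns `locus_id`, `disease`, `gene`,
#'   `n_categories`, `categories`, `E`.
#' @export
evidence_score <- function(records, weights = evidence_weights(),
                           mode = c("per_disease", "disease_agnostic")) {
  mode <- arg_match(mode)
  categories <- names(weights)
  unknown <- setdiff(unique(records$category), categories)
  if (length(unknown) > 0) {
    abort(paste0("unknown evidence categor(ies): ",
                 paste(unknown, collapse = ", ")))
  }
  ctx <- if (mode == "per_disease") {
    records
  } else {
    mutate(records, disease = "ALL")
  }
  ctx %>%
    distinct(.data$locus_id, .data$disease, .data$gene, .data$category) %>%
    group_by(.data$locus_id, .data$disease, .data$gene) %>%
    summarise(n_categories = n(),
              categories = paste(sort(unique(.data$category)),
                                 collapse = ";"),
              E = sum(weights[unique(.data$category)]),
              .groups = "drop")
}

#' Locus-adjusted confidence scores
#'
#' Adjusts each gene's total evidence score by the best-supported competing
#' gene in the same locus context: `CS_gl = E_g - max(E_g' : g' != g)`,
#' with the empty maximum defined as 0, so a gene alone in its locus keeps
#' `CS = E`. At most one gene per locus context can have `CS > 0`; ties at
#' the top give every tied gene `CS = 0`.
#'
#' @param scores Output of [evidence_score()].
#' @return A `gene_score_table` tibble: the input plus a `CS` column.
#' @export
confidence_score <- function(scores) {
  out <- scores %>%
    group_by(.data$locus_id, .data$disease) %>%
    mutate(CS = {
      if (n() == 1) {
        .data$E
      } else {
        best <- max(.data$E)
        second <- vapply(seq_along(.data$E), function(i) {
          max(.data$E[-i])
        }, numeric(1))
        .data$E - second
      }
    }) %>%
    ungroup()
  class(out) <- c("gene_score_table", class(out))
  out
}

#' Score genes from a catalog of prioritization evidence
#'
#' Convenience wrapper: [evidence_score()] then [confidence_score()].
#'
#' @inheritParams evidence_score
#' @return A `gene_score_table` tibble.
#' @export
score_genes <- function(records, weights = evidence_weights(),
                        mode = c("per_disease", "disease_agnostic")) {
  confidence_score(evidence_score(records, weights, mode))
}

#' Rank genes by confidence score
#'
#' Sorts by descending confidence score, then descending total evidence
#' score, then gene symbol (a deterministic tie-break), and truncates to
#' `top_k` rows.
#'
#' @param table A `gene_score_table` (see [score_genes()]).
#' @param top_k Rows to keep (default 25).
#' @return The ranked, truncated tibble with a `rank` column.
#' @export
rank_genes <- function(table, top_k = 25) {
  table %>%
    arrange(desc(.data$CS), desc(.data$E), .data$gene) %>%
    mutate(rank = row_number()) %>%
    head(top_k)
}

#' Pairwise agreement between gene-prioritization strategies
#'
#' For every pair of evidence categories, over the analysis units (locus-by-
#' disease combinations, or loci) dissected by both, reports the frequency
#' with which the two strategies prioritize at least one common gene. Pairs
#' co-dissecting fewer than `min_co_dissected` units are masked (`NA`).
#'
#' @param records A genes catalog tibble.
#' @param min_co_dissected Minimum units co-dissected for a cell to be
#'   reported (default 5).
#' @param unit `"locus_by_disease"` or `"locus"`.
#' @param categories Category vocabulary (defines the matrix rows/columns).
#' @return A tibble with `category_a`, `category_b`, `n_units`,
#'   `overlap_freq` for every unordered category pair.
#' @export
strategy_overlap <- function(records, min_co_dissected = 5,
                             unit = c("locus_by_disease", "locus"),
                             categories = evidence_categories()) {
  unit <- arg_match(unit)
  stopifnot(min_co_dissected >= 1)
  keys <- if (unit == "locus_by_disease") c("locus_id", "disease") else
    "locus_id"
  per_unit <- records
  per_unit$unit <- do.call(paste, c(unname(as.list(records[keys])),
                                    sep = "\r"))
  per_unit <- per_unit %>%
    group_by(.data$unit, .data$category) %>%
    summarise(genes = list(unique(.data$gene)), .groups = "drop")
  prs <- utils::combn(categories, 2)
  purrr::map_dfr(seq_len(ncol(prs)), function(k) {
    ca <- prs[1, k]
    cb <- prs[2, k]
    ua <- filter(per_unit, .data$category == ca)
    ub <- filter(per_unit, .data$category == cb)
    both <- dplyr::inner_join(ua, ub, by = "unit",
                              suffix = c("_a", "_b"))
    n_units <- nrow(both)
    freq <- if (n_units >= min_co_dissected) {
      mean(purrr::map2_lgl(both$genes_a, both$genes_b,
                           ~ length(intersect(.x, .y)) > 0))
    } else {
      NA_real_
    }
    tibble(category_a = ca, category_b = cb, n_units = n_units,
           overlap_freq = freq)
  })
}

#' @describeIn score_genes Bar chart of the top-ranked genes by confidence
#'   score.
#' @param x A `gene_score_table`.
#' @param top_k Genes to display.
#' @param ... Unused.
#' @export
autoplot.gene_score_table <- function(x, top_k = 25, ...) {
  top <- rank_genes(x, top_k)
  top$label <- paste0(top$gene, " (", top$locus_id, ", ", top$disease, ")")
  ggplot2::ggplot(top, ggplot2::aes(
    x = stats::reorder(.data$label, .data$CS), y = .data$CS)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "confidence score (CS)",
                  title = paste("Top", nrow(top), "prioritized genes")) +
    ggplot2::theme_minimal()
}
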