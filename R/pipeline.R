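#' Run the catalog analysis pipeline end to end
#'
#' Generates (or accepts) a fine-mapping catalog and chains the catalog
#' statistics, cross-disease comparisons and gene confidence scoring into
#' one result list. With a `catalog_config`, the synthetic generator
#' supplies the catalog and the ground truth is carried through.
#'
#' @param catalog A [catalog_config()] (synthetic run) or a list with
#'   elements `signals`, `variants`, `genes`.
#' @param weights An [evidence_weights()] vector.
#' @param top_k Genes to keep in the rankings.
#' @return A list: the input tables (and `truth` when synthetic), plus
#'   `multi_signal`, `lead_vs_additional`, `prioritization`, `overlap`,
#'   `concordance`, `scores_per_disease`, `scores_agnostic`,
#'   `top_genes_per_disease`, `top_genes_agnostic`.
#' @export
run_catalog_pipeline <- function(catalog = catalog_config(),
                                 weights = evidence_weights(),
                                 top_k = 25) {
  if (inherits(catalog, "catalog_config")) {
    catalog <- sim_catalog(catalog)
  }
  stopifnot(all(c("signals", "variants", "genes") %in% names(catalog)))
  scores_pd <- score_genes(catalog$genes, weights, "per_disease")
  scores_da <- score_genes(catalog$genes, weights, "disease_agnostic")
  c(catalog,
    list(
      multi_signal = multi_signal_loci(catalog$signals),
      lead_vs_additional = lead_vs_additional(catalog$signals),
      prioritization = prioritization_summary(catalog$variants),
      overlap = variant_overlap(catalog$variants),
      concordance = direction_concordance(catalog$variants),
      scores_per_disease = scores_pd,
      scores_agnostic = scores_da,
      top_genes_per_disease = rank_genes(scores_pd, top_k),
      top_genes_agnostic = rank_genes(scores_da, top_k)))
}
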