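#' Fold an allele frequency to the minor allele
#'
#' @param af Allele frequency/frequencies in `[0, 1]`.
#' @return `min(af, 1 - af)`.
#' @export
fold_maf <- function(af) {
  if (any(af < 0 | af > 1, na.rm = TRUE)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  pmin(af, 1 - af)
}

#' Classify a minor-allele frequency into common/low/rare
#'
#' Frequencies above 0.5 are folded to the minor allele first. Classes:
#' common for `AF > 0.1`, low for `0.01 < AF <= 0.1`, rare for `AF <= 0.01`.
#' The closed upper bounds at 0.1 and 0.01 are this package's convention;
#' the usual class definitions leave the exact boundaries unassigned.
#'
#' @param af Allele frequency/frequencies in `[0, 1]`.
#' @return Factor with levels `common`, `low`, `rare`.
#' @export
classify_af <- function(af) {
  maf <- fold_maf(af)
  cls <- case_when(maf > 0.1 ~ "common",
                   maf > 0.01 ~ "low",
                   TRUE ~ "rare")
  factor(cls, levels = c("common", "low", "rare"))
}

#' Loci with allelic heterogeneity
#'
#' A locus is multi-signal when at least one study reports two or more
#' independent association signals for it (union over studies and diseases).
#'
#' @param signals A signals catalog tibble.
#' @return A tibble with one row per locus: `locus_id`, `max_signals` (the
#'   largest per-study, per-disease signal count), and logical
#'   `multi_signal`. `sum(multi_signal)` is the headline count of loci with
#'   allelic heterogeneity.
#' @export
multi_signal_loci <- function(signals) {
  if (nrow(signals) == 0) {
    return(tibble(locus_id = character(), max_signals = integer(),
                  multi_signal = logical()))
  }
  signals %>%
    group_by(.data$locus_id, .data$disease, .data$study_id) %>%
    summarise(n_signals = max(.data$signal_rank), .groups = "drop") %>%
    group_by(.data$locus_id) %>%
    summarise(max_signals = as.integer(max(.data$n_signals)),
              .groups = "drop") %>%
    mutate(multi_signal = .data$max_signals >= 2)
}

# textbook Welch two-sample comparison of numeric vectors a (additional)
# vs b (lead); delegated to stats::t.test
welch_compare <- function(a, b, metric) {
  ht <- t.test(a, b)
  tibble(metric = metric,
         mean_additional = mean(a), mean_lead = mean(b),
         n_additional = length(a), n_lead = length(b),
         t_statistic = unname(ht$statistic),
         dof = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Compare additional versus lead signals at multi-signal loci
#'
#' At loci with allelic heterogeneity, additional (conditionally
#' independent) signals tend to be rarer, larger-effect variants than the
#' lead signals. This compares minor-allele frequency (risk-allele frequency
#' folded at 0.5) and risk-allele odds ratio between additional signals
#' (rank >= 2) and lead signals (rank 1), restricted to multi-signal loci,
#' with Welch's unequal-variance t test.
#'
#' @param signals A signals catalog tibble.
#' @param exclude_hla Drop the HLA locus (`6p21.32`)? Default `TRUE`; its
#'   haplotype-level reporting is not comparable with ordinary signals.
#' @param dedupe Deduplicate repeated reports of the same (locus, disease,
#'   signal_rank), keeping the first-listed study? Default `TRUE`.
#' @return A tibble with one row per metric (`maf`, `odds_ratio`): group
#'   means and sizes, Welch t statistic, Welch-Satterthwaite degrees of
#'   freedom, and the two-sided p-value.
#' @export
lead_vs_additional <- function(signals, exclude_hla = TRUE, dedupe = TRUE) {
  s <- signals
  if (exclude_hla) s <- filter(s, .data$locus_id != "6p21.32")
  if (dedupe) {
    s <- distinct(s, .data$locus_id, .data$disease, .data$signal_rank,
                  .keep_all = TRUE)
  }
  multi <- multi_signal_loci(s) %>% filter(.data$multi_signal)
  s <- semi_join(s, multi, by = "locus_id") %>%
    mutate(maf = fold_maf(.data$risk_allele_freq),
           group = if_else(.data$signal_rank >= 2, "additional", "lead"))
  a <- filter(s, .data$group == "additional")
  b <- filter(s, .data$group == "lead")
  if (nrow(a) < 2 || nrow(b) < 2) {
    abort("need at least 2 lead and 2 additional signals at multi-signal loci")
  }
  bind_rows(
    welch_compare(a$maf, b$maf, "maf"),
    welch_compare(a$odds_ratio, b$odds_ratio, "odds_ratio"))
}

#' Summary of variant-prioritization results
#'
#' Counts are over locus-by-disease association signals (not studies): a
#' signal is counted once per method class it was fine-mapped with, flagged
#' coding-damaging when any of its prioritized variants is pLOF or predicted
#' damaging missense, and the median number of statistically prioritized
#' variants is taken over signals with statistical fine-mapping.
#'
#' @param variants A variants catalog tibble (one row per prioritized
#'   variant).
#' @return A one-row tibble: `n_signals`, `n_statistical`, `n_functional`,
#'   `n_integrative`, `n_coding_damaging`, `n_noncoding`,
#'   `median_statistical_variants`.
#' @export
prioritization_summary <- function(variants) {
  if (nrow(variants) == 0) {
    return(tibble(n_signals = 0L, n_statistical = 0L, n_functional = 0L,
                  n_integrative = 0L, n_coding_damaging = 0L,
                  n_noncoding = 0L,
                  median_statistical_variants = NA_real_))
  }
  per_signal <- variants %>%
    group_by(.data$locus_id, .data$disease) %>%
    summarise(
      statistical = any(.data$method_class == "statistical"),
      functional = any(.data$method_class == "functional"),
      integrative = any(.data$method_class == "integrative"),
      coding_damaging = any(.data$coding_class %in%
                              c("pLOF", "missense_damaging"), na.rm = TRUE),
      n_statistical_variants = n_distinct(
        .data$variant_id[.data$method_class == "statistical"]),
      .groups = "drop")
  tibble(
    n_signals = nrow(per_signal),
    n_statistical = sum(per_signal$statistical),
    n_functional = sum(per_signal$functional),
    n_integrative = sum(per_signal$integrative),
    n_coding_damaging = sum(per_signal$coding_damaging),
    n_noncoding = sum(!per_signal$coding_damaging),
    median_statistical_variants = median(
      per_signal$n_statistical_variants[per_signal$statistical]))
}

#' Therapeutic-direction hypothesis from loss-of-function allele effects
#'
#' When a loss- (or partial-loss-) of-function allele increases disease
#' risk, restoring or boosting the gene product is the therapeutic
#' hypothesis (agonist); when the LOF allele protects, blocking the product
#' is (antagonist). Unknown directions are reported explicitly as
#' `undetermined`, never silently defaulted.
#'
#' @param lof_allele_effect Character vector with values `"risk"`,
#'   `"protective"`, or anything else/`NA` for unknown.
#' @return Factor with levels `agonist`, `antagonist`, `undetermined`.
#' @export
therapeutic_direction <- function(lof_allele_effect) {
  out <- case_when(lof_allele_effect == "risk" ~ "agonist",
                   lof_allele_effect == "protective" ~ "antagonist",
                   TRUE ~ "undetermined")
  factor(out, levels = c("agonist", "antagonist", "undetermined"))
}
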