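#' Configuration for the synthetic fine-mapping catalog generator
#'
#' The generator emulates the statistical structure of a curated
#' fine-mapping catalog with known ground truth. Defaults encode the
#' headline rates of published autoimmune fine-mapping syntheses: 22% of
#' loci with allelic heterogeneity; additional signals rarer (mean MAF
#' 0.09 vs 0.25) and larger-effect (mean OR 1.52 vs 1.26) than lead
#' signals; a median of 8 statistically prioritized variants per signal;
#' 11.5% of signals carrying a coding-damaging variant; a shared
#' prioritized variant at 41% of cross-disease locus comparisons, with
#' 20.5% of shared variants flipping direction of effect between diseases.
#'
#' @param n_loci Number of GWAS loci.
#' @param n_diseases Diseases drawn from [disease_codes()] (each locus is
#'   fine-mapped for two of them, forming one disease pair per locus).
#' @param genes_per_locus Genes per locus; the first is the planted
#'   trait-relevant gene.
#' @param p_multi_signal Probability a locus has allelic heterogeneity.
#' @param p_shared_variant Probability the locus's two diseases share a
#'   prioritized variant.
#' @param p_direction_flip Probability a shared variant has opposite
#'   directions of effect in the two diseases.
#' @param p_coding_damaging Probability a signal's prioritized set contains
#'   a pLOF/damaging-missense variant.
#' @param p_functional,p_integrative Probability a signal is additionally
#'   fine-mapped by functional experiments / integrative algorithms
#'   (statistical fine-mapping is always present).
#' @param lambda_statistical_variants Poisson rate; statistical
#'   prioritized-set sizes are `1 + Poisson(lambda)` (median 8 at the
#'   default 7).
#' @param category_sensitivity Per-category probability that the true gene
#'   emits evidence (scalar or length 7).
#' @param category_noise Per-category probability that each decoy gene
#'   emits evidence (scalar or length 7).
#' @param lead_maf_shape,additional_maf_shape Beta shape pairs for lead and
#'   additional-signal minor-allele frequencies (means 0.25 and 0.09).
#' @param lead_or_meanlog,additional_or_meanlog,or_sdlog Log-normal
#'   parameters for risk-allele odds ratios (arithmetic means 1.26, 1.52).
#' @param seed RNG seed.
#' @return A `catalog_config` list.
#' @export
catalog_config <- function(n_loci = 150, n_diseases = 11,
                           genes_per_locus = 4,
                           p_multi_signal = 0.22,
                           p_shared_variant = 0.41,
                           p_direction_flip = 0.205,
                           p_coding_damaging = 0.115,
                           p_functional = 0.079,
                           p_integrative = 0.061,
                           lambda_statistical_variants = 7,
                           category_sensitivity = 0.9,
                           category_noise = 0.1,
                           lead_maf_shape = c(2.5, 7.5),
                           additional_maf_shape = c(1.8, 18.2),
                           lead_or_meanlog = log(1.26) - 0.1^2 / 2,
                           additional_or_meanlog = log(1.52) - 0.15^2 / 2,
                           or_sdlog = c(0.1, 0.15),
                           seed = 1) {
  n_cat <- length(evidence_categories())
  expand <- function(p) {
    p <- rep(p, length.out = n_cat)
    stopifnot(all(p >= 0 & p <= 1))
    setNames(p, evidence_categories())
  }
  probs <- c(p_multi_signal, p_shared_variant, p_direction_flip,
             p_coding_damaging, p_functional, p_integrative)
  stopifnot(all(probs >= 0 & probs <= 1), genes_per_locus >= 1,
            n_loci >= 1, n_diseases >= 2,
            n_diseases <= length(disease_codes()))
  structure(
    list(n_loci = n_loci, n_diseases = n_diseases,
         genes_per_locus = genes_per_locus,
         p_multi_signal = p_multi_signal,
         p_shared_variant = p_shared_variant,
         p_direction_flip = p_direction_flip,
         p_coding_damaging = p_coding_damaging,
         p_functional = p_functional, p_integrative = p_integrative,
         lambda_statistical_variants = lambda_statistical_variants,
         category_sensitivity = expand(category_sensitivity),
         category_noise = expand(category_noise),
         lead_maf_shape = lead_maf_shape,
         additional_maf_shape = additional_maf_shape,
         lead_or_meanlog = lead_or_meanlog,
         additional_or_meanlog = additional_or_meanlog,
         or_sdlog = or_sdlog, seed = seed),
    class = "catalog_config")
}

# draw a risk-allele frequency given a MAF Beta shape (risk allele is the
# minor allele half the time)
draw_raf <- function(n, shape) {
  maf <- stats::rbeta(n, shape[1], shape[2])
  flip <- rbinom(n, 1, 0.5) == 1
  ifelse(flip, 1 - maf, maf)
}

#' Generate a synthetic fine-mapping catalog with ground truth
#'
#' Produces the three catalog tables consumed by the pipeline (signals,
#' prioritized variants, gene evidence) plus the generating ground truth.
#' Each locus is fine-mapped for two diseases; every signal has a
#' statistical prioritized-variant set; variant IDs within a locus are
#' drawn without replacement, so two diseases share a variant only when the
#' generator plants one.
#'
#' @param config A [catalog_config()].
#' @return A list with elements `signals`, `variants`, `genes` (catalog
#'   tibbles) and `truth` (per-locus tibble of planted values: true gene,
#'   signal count, shared-variant and direction-flip indicators).
#' @export
sim_catalog <- function(config = catalog_config()) {
  with_seed(config$seed, {
    diseases <- disease_codes()[seq_len(config$n_diseases)]
    cats <- evidence_categories()
    loci <- tibble(
      idx = seq_len(config$n_loci),
      chrom = as.character(((seq_len(config$n_loci) - 1) %% 22) + 1),
      locus_id = paste0(((seq_len(config$n_loci) - 1) %% 22) + 1, "q",
                        10 + (seq_len(config$n_loci) - 1) %/% 22 + 1, ".",
                        (seq_len(config$n_loci) - 1) %% 3 + 1))
    loci$locus_id <- make.unique(loci$locus_id, sep = "_")

    signals <- list()
    variants <- list()
    genes <- list()
    truth <- list()

    for (i in seq_len(config$n_loci)) {
      lid <- loci$locus_id[i]
      chrom <- loci$chrom[i]
      dis <- sort(sample(diseases, 2))
      base <- i * 1e6
      pool <- base + sample.int(5e5, 500)  # unique positions within locus
      pool_ids <- paste0("chr", chrom, ":", pool, ":A:G")
      next_id <- 1
      take_ids <- function(k) {
        out <- pool_ids[next_id:(next_id + k - 1)]
        next_id <<- next_id + k
        out
      }

      multi <- rbinom(1, 1, config$p_multi_signal) == 1
      n_extra <- if (multi) 1 + rpois(1, 0.7) else 0
      shared <- rbinom(1, 1, config$p_shared_variant) == 1
      flip <- shared && rbinom(1, 1, config$p_direction_flip) == 1
      shared_id <- if (shared) take_ids(1) else NA_character_

      for (d_i in seq_along(dis)) {
        d <- dis[d_i]
        study <- paste0("S", i, "_", d)
        ranks <- if (d_i == 1) seq_len(1 + n_extra) else 1L
        # total statistically prioritized variants for this locus-by-disease
        # combination: 1 + Poisson(lambda), split across its signals, so the
        # per-combination count has the configured median
        total_var <- max(length(ranks),
                         1 + rpois(1, config$lambda_statistical_variants))
        extra_alloc <- if (total_var > length(ranks)) {
          tabulate(sample.int(length(ranks), total_var - length(ranks),
                              replace = TRUE), nbins = length(ranks))
        } else {
          rep(0L, length(ranks))
        }
        sizes <- 1L + extra_alloc
        for (r in ranks) {
          lead <- r == 1
          raf <- draw_raf(1, if (lead) config$lead_maf_shape else
            config$additional_maf_shape)
          or <- stats::rlnorm(1,
                              if (lead) config$lead_or_meanlog else
                                config$additional_or_meanlog,
                              config$or_sdlog[if (lead) 1 else 2])
          sig_var <- take_ids(1)
          signals[[length(signals) + 1]] <- tibble(
            locus_id = lid, chrom = chrom, disease = d,
            signal_rank = as.integer(r), variant_id = sig_var,
            risk_allele_freq = raf, odds_ratio = or,
            coding_class = "unknown", study_id = study)

          n_var <- sizes[r]
          shared_here <- lead && shared
          if (shared_here) {
            # the planted shared variant fills one slot of the lead set
            ids <- c(sig_var, shared_id,
                     if (n_var > 2) take_ids(n_var - 2))
            n_var <- length(ids)
          } else {
            ids <- c(sig_var, if (n_var > 1) take_ids(n_var - 1))
          }
          coding <- rep("noncoding", n_var)
          # planted per locus-by-disease signal (on the lead rank), so the
          # summary-level coding-damaging rate equals p_coding_damaging
          if (lead && rbinom(1, 1, config$p_coding_damaging) == 1) {
            coding[sample.int(n_var, 1)] <-
              sample(c("pLOF", "missense_damaging"), 1, prob = c(0.3, 0.7))
          }
          dir <- rep("risk", n_var)
          if (shared_here && d_i == 2 && flip) {
            dir[ids == shared_id] <- "protective"
          }
          variants[[length(variants) + 1]] <- tibble(
            locus_id = lid, chrom = chrom, disease = d,
            signal_rank = as.integer(r), method_class = "statistical",
            variant_id = ids, coding_class = coding,
            direction_of_effect = dir, study_id = study)
          for (mc in c("functional", "integrative")) {
            p_mc <- if (mc == "functional") config$p_functional else
              config$p_integrative
            if (rbinom(1, 1, p_mc) == 1) {
              sub <- sample(ids, min(length(ids), 1 + rpois(1, 1)))
              variants[[length(variants) + 1]] <- tibble(
                locus_id = lid, chrom = chrom, disease = d,
                signal_rank = as.integer(r), method_class = mc,
                variant_id = sub,
                coding_class = coding[match(sub, ids)],
                direction_of_effect = dir[match(sub, ids)],
                study_id = paste0(study, "_", mc))
            }
          }
        }
      }

      gene_names <- sprintf("GENE%03d%s", i,
                            LETTERS[seq_len(config$genes_per_locus)])
      true_gene <- gene_names[1]
      for (d in dis) {
        for (ci in seq_along(cats)) {
          if (rbinom(1, 1, config$category_sensitivity[ci]) == 1) {
            genes[[length(genes) + 1]] <- tibble(
              locus_id = lid, chrom = chrom, disease = d,
              gene = true_gene, category = cats[ci],
              study_id = paste0("G", i, "_", d, "_", ci))
          }
          for (g in gene_names[-1]) {
            if (rbinom(1, 1, config$category_noise[ci]) == 1) {
              genes[[length(genes) + 1]] <- tibble(
                locus_id = lid, chrom = chrom, disease = d,
                gene = g, category = cats[ci],
                study_id = paste0("G", i, "_", d, "_", ci, "_", g))
            }
          }
        }
      }

      truth[[i]] <- tibble(
        locus_id = lid, chrom = chrom,
        disease_a = dis[1], disease_b = dis[2],
        true_gene = true_gene, multi_signal = multi,
        n_signals = as.integer(1 + n_extra),
        shared_variant = shared, direction_flip = flip,
        shared_variant_id = shared_id)
    }

    out <- list(signals = bind_rows(signals),
                variants = bind_rows(variants),
                genes = bind_rows(genes),
                truth = bind_rows(truth))
    attr(out$signals, "catalog_kind") <- "signals"
    attr(out$variants, "catalog_kind") <- "variants"
    attr(out$genes, "catalog_kind") <- "genes"
    out
  })
}

#' Generate synthetic abstracts with planted screening outcomes
#'
#' Builds templated abstract records whose texts pass the two screening
#' stages at the requested rates, with the planted outcome recorded per
#' record.
#'
#' @param n Number of abstracts.
#' @param p_stage1 Probability an abstract carries GWAS + mechanism terms.
#' @param p_stage2_given_stage1 Probability a stage-1 abstract also carries
#'   an autoimmune-disease term.
#' @param seed RNG seed.
#' @return A list with `abstracts` (catalog tibble) and `truth` (tibble of
#'   planted `stage1`/`stage2` flags).
#' @export
sim_abstracts <- function(n, p_stage1 = 0.3, p_stage2_given_stage1 = 0.5,
                          seed = 1) {
  stopifnot(p_stage1 >= 0, p_stage1 <= 1,
            p_stage2_given_stage1 >= 0, p_stage2_given_stage1 <= 1)
  with_seed(seed, {
    stage1 <- rbinom(n, 1, p_stage1) == 1
    stage2 <- stage1 & rbinom(n, 1, p_stage2_given_stage1) == 1
    disease_phrases <- c("Crohn disease", "ulcerative colitis",
                         "rheumatoid arthritis", "type 1 diabetes",
                         "multiple sclerosis", "psoriasis")
    mech <- c("causal", "functional", "mechanistic")
    text <- character(n)
    for (i in seq_len(n)) {
      if (stage2[i]) {
        text[i] <- paste0(
          "A genome-wide association study of ",
          sample(disease_phrases, 1), " fine-mapped the locus and ",
          "identified a ", sample(mech, 1), " variant.")
      } else if (stage1[i]) {
        text[i] <- paste0(
          "A GWAS of adult height identified ", sample(mech, 1),
          " enhancer variants in skeletal tissue.")
      } else if (rbinom(1, 1, 0.5) == 1) {
        text[i] <- "A GWAS of blood pressure identified twelve new loci."
      } else {
        text[i] <- "We profiled the transcriptome of liver organoids."
      }
    }
    abstracts <- tibble(
      abstract_id = sprintf("A%05d", seq_len(n)),
      pub_date = as.Date("2005-01-01") +
        sample.int(5400, n, replace = TRUE),
      text = text)
    attr(abstracts, "catalog_kind") <- "abstracts"
    list(abstracts = abstracts,
         truth = tibble(abstract_id = abstracts$abstract_id,
                        stage1 = stage1, stage2 = stage2))
  })
}
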