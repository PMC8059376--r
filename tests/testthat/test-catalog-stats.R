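test_that("allele-frequency classes partition [0, 0.5] with folded input", {
  expect_equal(as.character(classify_af(c(0.25, 0.05, 0.005))),
               c("common", "low", "rare"))
  # folding: 0.95 is a 0.05 minor allele
  expect_equal(as.character(classify_af(0.95)), "low")
  # closed upper bounds at the class boundaries
  expect_equal(as.character(classify_af(c(0.1, 0.01))), c("low", "rare"))
  expect_equal(as.character(classify_af(c(0.1 + 1e-12, 0.01 + 1e-12))),
               c("common", "low"))
  # total function: every value gets exactly one class
  withr::with_seed(5, {
    x <- runif(200)
    expect_false(any(is.na(classify_af(x))))
  })
  expect_error(classify_af(1.2), "\\[0, 1\\]")
})

test_that("multi-signal status uses the any-study rule", {
  expect_equal(nrow(multi_signal_loci(toy_signals()[0, ])), 0)

  s <- dplyr::bind_rows(
    variantless <- toy_signals()[1, ],  # rank-1 only, study S1
    dplyr::mutate(toy_signals()[1, ], study_id = "S9", signal_rank = 3L))
  ms <- multi_signal_loci(s)
  expect_equal(ms$max_signals[ms$locus_id == "1q24.3"], 3L)
  expect_true(ms$multi_signal[ms$locus_id == "1q24.3"])

  # monotone under catalog union
  cat1 <- sim_catalog(catalog_config(n_loci = 15, seed = 1))$signals
  cat2 <- sim_catalog(catalog_config(n_loci = 15, seed = 2))$signals
  both <- multi_signal_loci(dplyr::bind_rows(cat1, cat2))
  expect_gte(sum(both$multi_signal), sum(multi_signal_loci(cat1)$multi_signal))
  expect_gte(sum(both$multi_signal), sum(multi_signal_loci(cat2)$multi_signal))
})

test_that("multi-signal count recovers the generator's planted loci", {
  cat <- sim_catalog(catalog_config(n_loci = 40, seed = 12))
  ms <- multi_signal_loci(cat$signals)
  expect_equal(sum(ms$multi_signal), sum(cat$truth$multi_signal))
  expect_equal(sort(ms$locus_id[ms$multi_signal]),
               sort(cat$truth$locus_id[cat$truth$multi_signal]))
})

mk_multi_catalog <- function(lead_maf, extra_maf, lead_or, extra_or) {
  n <- length(lead_maf)
  dplyr::bind_rows(
    tibble::tibble(locus_id = paste0("L", seq_len(n)), chrom = "1",
                   disease = "CD", signal_rank = 1L,
                   variant_id = paste0("rsA", seq_len(n)),
                   risk_allele_freq = lead_maf, odds_ratio = lead_or,
                   coding_class = "noncoding", study_id = "S1"),
    tibble::tibble(locus_id = paste0("L", seq_len(n)), chrom = "1",
                   disease = "CD", signal_rank = 2L,
                   variant_id = paste0("rsB", seq_len(n)),
                   risk_allele_freq = extra_maf, odds_ratio = extra_or,
                   coding_class = "noncoding", study_id = "S1"))
}

test_that("lead-vs-additional comparison matches the textbook Welch oracle", {
  a <- c(0.05, 0.07, 0.09)  # additional-signal MAFs
  b <- c(0.10, 0.20, 0.30)  # lead-signal MAFs
  s <- mk_multi_catalog(b, a, c(1.2, 1.3, 1.25), c(1.5, 1.6, 1.45))
  got <- lead_vs_additional(s)
  maf_row <- got[got$metric == "maf", ]
  oracle <- welch_oracle(a, b)
  expect_equal(maf_row$t_statistic, oracle$t, tolerance = 1e-10)
  expect_equal(maf_row$dof, oracle$dof, tolerance = 1e-10)
  expect_equal(maf_row$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(maf_row$t_statistic, -2.21, tolerance = 0.01)
  expect_equal(maf_row$dof, 2.16, tolerance = 0.01)
  expect_lte(maf_row$dof, maf_row$n_additional + maf_row$n_lead - 2)

  or_row <- got[got$metric == "odds_ratio", ]
  or_oracle <- welch_oracle(c(1.5, 1.6, 1.45), c(1.2, 1.3, 1.25))
  expect_equal(or_row$t_statistic, or_oracle$t, tolerance = 1e-10)
})

test_that("Welch t equals the pooled t for equal-variance equal-n groups", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)  # same spread, same n
  s <- mk_multi_catalog(b / 10, a / 10, b, a)
  got <- lead_vs_additional(s)
  pooled <- t.test(a / 10, b / 10, var.equal = TRUE)
  maf_row <- got[got$metric == "maf", ]
  expect_equal(maf_row$t_statistic, unname(pooled$statistic),
               tolerance = 1e-10)
  expect_equal(maf_row$dof, unname(pooled$parameter), tolerance = 1e-10)
})

test_that("identical groups give t = 0 and p = 1", {
  vals <- c(0.1, 0.2, 0.3)
  s <- mk_multi_catalog(vals, vals, c(1.1, 1.2, 1.3), c(1.1, 1.2, 1.3))
  got <- lead_vs_additional(s)
  expect_equal(got$t_statistic, c(0, 0))
  expect_equal(got$p_value, c(1, 1))
})

test_that("HLA exclusion and per-signal deduplication are applied", {
  base <- mk_multi_catalog(c(0.3, 0.28, 0.31), c(0.05, 0.06, 0.07),
                           c(1.2, 1.25, 1.22), c(1.5, 1.55, 1.52))
  hla <- dplyr::mutate(mk_multi_catalog(0.49, 0.48, 1.01, 1.02)[1:2, ],
                       locus_id = "6p21.32")
  with_hla <- dplyr::bind_rows(base, hla)
  expect_equal(lead_vs_additional(with_hla), lead_vs_additional(base))
  incl <- lead_vs_additional(with_hla, exclude_hla = FALSE)
  expect_equal(incl$n_lead[1], 4)

  # a second study re-reporting the same signals must not double-count
  dup <- dplyr::bind_rows(base, dplyr::mutate(base, study_id = "S2",
                                              risk_allele_freq = 0.4))
  expect_equal(lead_vs_additional(dup), lead_vs_additional(base))
})

test_that("prioritization summaries count locus-by-disease signals", {
  empty <- prioritization_summary(variant_rows("L1", "CD", 1,
                                               "statistical", "rs1")[0, ])
  expect_equal(empty$n_signals, 0)

  v <- dplyr::bind_rows(
    variant_rows("L1", "CD", 1, "statistical", "rs1"),
    variant_rows("L2", "CD", 1, "statistical", paste0("rs", 2:9)),
    variant_rows("L3", "UC", 1, "statistical", paste0("rs", 10:109)))
  got <- prioritization_summary(v)
  expect_equal(got$n_signals, 3)
  expect_equal(got$median_statistical_variants, 8)

  # coding-damaging flag: any pLOF / damaging-missense prioritized variant
  v2 <- dplyr::bind_rows(
    variant_rows("L1", "CD", 1, "statistical", c("rs1", "rs2"),
                 coding = c("noncoding", "missense_damaging")),
    variant_rows("L2", "CD", 1, "functional", "rs3",
                 coding = "missense_benign"))
  got2 <- prioritization_summary(v2)
  expect_equal(got2$n_coding_damaging, 1)
  expect_equal(got2$n_noncoding, 1)
  expect_equal(got2$n_statistical, 1)
  expect_equal(got2$n_functional, 1)
})

test_that("planted coding-damaging fraction is recovered within binomial CI", {
  cat <- sim_catalog(catalog_config(n_loci = 150, seed = 33))
  got <- prioritization_summary(cat$variants)
  phat <- got$n_coding_damaging / got$n_signals
  expect_true(within_binom_ci(phat, 0.115, got$n_signals))
})

test_that("therapeutic direction maps LOF effects and never guesses", {
  expect_equal(as.character(therapeutic_direction(
    c("risk", "protective", NA, "other"))),
    c("agonist", "antagonist", "undetermined", "undetermined"))
})
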