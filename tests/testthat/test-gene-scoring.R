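mk_evidence <- function(locus, disease, gene, cats,
                        study = paste0("S_", gene)) {
  tibble::tibble(locus_id = locus, chrom = "1", disease = disease,
                 gene = gene, category = cats, study_id = study)
}

test_that("evidence weights enforce positivity and the category ordering", {
  w <- evidence_weights()
  expect_equal(unname(w[c("pLOF_missense_damaging",
                          "gene_based_association")]), c(2, 2))
  expect_error(evidence_weights(
    setNames(c(-1, rep(1, 6)), evidence_categories())), "positive")
  # eQTL colocalization outranking coding evidence is rejected
  bad <- setNames(rep(1, 7), evidence_categories())
  bad["molecular_qtl_colocalization"] <- 5
  expect_error(evidence_weights(bad), "largest")
  ok <- evidence_weights(setNames(c(4, 4, 2, 1, 1, 3, 1),
                                  evidence_categories()))
  expect_equal(unname(ok["network_coexpression"]), 3)
})

test_that("E is the weighted count of evidenced categories, deduplicated", {
  cats <- evidence_categories()
  ev <- mk_evidence("L1", "CD", "A", cats[c(1, 3)])
  e <- evidence_score(ev, evidence_weights())
  expect_equal(e$E, 2 + 1)

  # duplicate records within a category never double-count
  ev_dup <- dplyr::bind_rows(ev, dplyr::mutate(ev, study_id = "S_other"))
  expect_equal(evidence_score(ev_dup, evidence_weights())$E, 3)

  # saturation: all seven categories
  full <- evidence_score(mk_evidence("L1", "CD", "A", cats),
                         evidence_weights())
  expect_equal(full$E, sum(evidence_weights()))
  expect_equal(full$n_categories, 7)

  expect_error(evidence_score(mk_evidence("L1", "CD", "A", "telepathy")),
               "telepathy")
})

test_that("confidence scores subtract the best competing gene in the locus", {
  cats <- evidence_categories()
  ev <- dplyr::bind_rows(
    mk_evidence("L1", "CD", "A", cats[1:4]),      # E = 2+2+1+1 = 6...
    mk_evidence("L1", "CD", "B", cats[3]),        # E = 1
    mk_evidence("L1", "CD", "C", cats[4]))        # E = 1
  w <- setNames(c(2, 2, 1, 1, 1, 1, 1), cats)
  tbl <- score_genes(ev, evidence_weights(w))
  got <- setNames(tbl$CS, tbl$gene)
  # E = {A:6, B:1, C:1}: CS adjusts by the max of the others
  expect_equal(got[["A"]], 5)
  expect_equal(got[["B"]], -5)
  expect_equal(got[["C"]], -5)

  # numeric example: E = {5, 2, 1} -> CS = {3, -3, -4}
  ev2 <- dplyr::bind_rows(
    mk_evidence("L2", "CD", "A", cats[c(1, 3, 4, 5)]),  # 2+1+1+1 = 5
    mk_evidence("L2", "CD", "B", cats[c(3, 4)]),        # 2
    mk_evidence("L2", "CD", "C", cats[5]))              # 1
  tbl2 <- score_genes(ev2, evidence_weights(w))
  expect_equal(setNames(tbl2$CS, tbl2$gene),
               c(A = 3, B = -3, C = -4))

  # tie at the top: no winner
  tie <- score_genes(dplyr::bind_rows(
    mk_evidence("L3", "CD", "A", cats[3]),
    mk_evidence("L3", "CD", "B", cats[4])), evidence_weights(w))
  expect_equal(tie$CS, c(0, 0))

  # single-gene locus: empty competing set contributes 0
  lone <- score_genes(mk_evidence("L4", "CD", "A", cats[c(1, 3)]),
                      evidence_weights(w))
  expect_equal(lone$CS, lone$E)
  expect_equal(lone$CS, 3)
})

test_that("disease-agnostic pooling unions evidence across diseases", {
  cats <- evidence_categories()
  ev <- dplyr::bind_rows(
    mk_evidence("L1", "CD", "A", cats[1]),
    mk_evidence("L1", "UC", "A", cats[2]),
    mk_evidence("L1", "UC", "B", cats[3]))
  pd <- evidence_score(ev, mode = "per_disease")
  da <- evidence_score(ev, mode = "disease_agnostic")
  expect_equal(da$disease, rep("ALL", 2))
  expect_equal(da$E[da$gene == "A"], 4)  # categories 1 and 2 pooled
  # pooling can only add categories: agnostic E >= any per-disease E
  joined <- dplyr::left_join(pd, da, by = c("locus_id", "gene"),
                             suffix = c("_pd", "_da"))
  expect_true(all(joined$E_da >= joined$E_pd))
})

test_that("score invariants hold on generated catalogs", {
  cat <- sim_catalog(catalog_config(n_loci = 25, seed = 19))
  w1 <- evidence_weights()
  tbl <- score_genes(cat$genes, w1)
  # at most one positive confidence score per locus context
  per_ctx <- dplyr::summarise(
    dplyr::group_by(tbl, locus_id, disease),
    n_pos = sum(CS > 0), .groups = "drop")
  expect_true(all(per_ctx$n_pos <= 1))

  # scale invariance: weights * c scales E and CS, preserves ranking
  c_mult <- 3.7
  tbl2 <- score_genes(cat$genes, evidence_weights(c_mult * unclass(w1)))
  expect_equal(tbl2$E, c_mult * tbl$E, tolerance = 1e-12)
  expect_equal(tbl2$CS, c_mult * tbl$CS, tolerance = 1e-12)
  # ranking is scale-free; round away float-addition noise before sorting
  rg <- function(t) {
    t$CS <- round(t$CS, 8)
    t$E <- round(t$E, 8)
    rank_genes(t, 50)$gene
  }
  expect_equal(rg(dplyr::mutate(tbl2, CS = CS / c_mult, E = E / c_mult)),
               rg(tbl))

  # two-gene loci: antisymmetric confidence scores
  two <- dplyr::filter(dplyr::add_count(tbl, locus_id, disease), n == 2)
  sums <- dplyr::summarise(dplyr::group_by(two, locus_id, disease),
                           s = sum(CS), .groups = "drop")
  expect_true(all(abs(sums$s) < 1e-12))
})

test_that("rankings put locus winners first and truncate at top_k", {
  cats <- evidence_categories()
  ev <- dplyr::bind_rows(
    mk_evidence("L1", "CD", "WIN1", cats[1:5]),
    mk_evidence("L1", "CD", "LOSE1", cats[6]),
    mk_evidence("L2", "CD", "WIN2", cats[1:3]),
    mk_evidence("L2", "CD", "LOSE2", cats[7]))
  tbl <- score_genes(ev)
  ranked <- rank_genes(tbl, 10)
  expect_equal(nrow(ranked), 4)  # top_k larger than the table
  expect_equal(ranked$gene[1:2], c("WIN1", "WIN2"))
  expect_true(all(ranked$CS[1:2] > 0), TRUE)
  expect_equal(nrow(rank_genes(tbl, 3)), 3)
})

test_that("planted true genes win their loci at high evidence fidelity", {
  cat <- sim_catalog(catalog_config(n_loci = 50, genes_per_locus = 4,
                                    category_sensitivity = 0.9,
                                    category_noise = 0.1, seed = 27))
  tbl <- score_genes(cat$genes, mode = "per_disease")
  winners <- dplyr::slice_max(dplyr::group_by(tbl, locus_id, disease),
                              CS, n = 1, with_ties = FALSE)
  winners <- dplyr::left_join(dplyr::ungroup(winners),
                              cat$truth[, c("locus_id", "true_gene")],
                              by = "locus_id")
  expect_gte(mean(winners$gene == winners$true_gene), 0.9)
})

test_that("strategy overlap frequencies are computed per co-dissected unit", {
  cats <- evidence_categories()
  # identical gene calls by two strategies on 6 units: frequency 1
  ev <- purrr::map_dfr(1:6, function(i) dplyr::bind_rows(
    mk_evidence(paste0("L", i), "CD", paste0("G", i), cats[1]),
    mk_evidence(paste0("L", i), "CD", paste0("G", i), cats[2])))
  so <- strategy_overlap(ev, min_co_dissected = 5)
  cell <- so[so$category_a == cats[1] & so$category_b == cats[2], ]
  expect_equal(cell$n_units, 6)
  expect_equal(cell$overlap_freq, 1)
  # categories that never co-dissect a unit are masked
  never <- so[so$category_a == cats[1] & so$category_b == cats[3], ]
  expect_true(is.na(never$overlap_freq))

  # planted 50% agreement on 20 units
  ev50 <- purrr::map_dfr(1:20, function(i) dplyr::bind_rows(
    mk_evidence(paste0("L", i), "CD", "SAME", cats[1]),
    mk_evidence(paste0("L", i), "CD",
                if (i <= 10) "SAME" else "OTHER", cats[2])))
  so50 <- strategy_overlap(ev50, min_co_dissected = 5)
  f <- so50$overlap_freq[so50$category_a == cats[1] &
                           so50$category_b == cats[2]]
  expect_equal(f, 0.5)
  expect_true(within_binom_ci(f, 0.5, 20))

  # unit = locus pools diseases
  ev_l <- dplyr::bind_rows(
    mk_evidence("L1", "CD", "A", cats[1]),
    mk_evidence("L1", "UC", "A", cats[2]))
  by_ld <- strategy_overlap(ev_l, min_co_dissected = 1)
  by_l <- strategy_overlap(ev_l, min_co_dissected = 1, unit = "locus")
  expect_equal(by_ld$n_units[1], 0)
  expect_equal(by_l$n_units[1], 1)
})
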