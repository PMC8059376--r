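# Independent oracles and tiny in-code fixtures shared across test files.

# textbook Welch two-sample t: statistic, Welch-Satterthwaite dof, p
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t_stat, dof = dof, p = 2 * pt(-abs(t_stat), dof))
}

# naive O(H M^2) two-locus counting LD oracle: D from haplotype counts,
# normalized by allele-frequency products
naive_ld <- function(alleles) {
  m <- ncol(alleles)
  h <- nrow(alleles)
  p <- colMeans(alleles)
  r <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      p11 <- sum(alleles[, i] == 1 & alleles[, j] == 1) / h
      d <- p11 - p[i] * p[j]
      r[i, j] <- d / sqrt(p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
    }
  }
  r
}

# small panel with exactly known columns
toy_panel <- function(cols, positions = seq_along(cols) * 10) {
  haplotype_panel(do.call(cbind, cols), positions)
}

# a hand-written valid signals catalog: two loci, one with two signals
toy_signals <- function() {
  tibble::tribble(
    ~locus_id, ~chrom, ~disease, ~signal_rank, ~variant_id,
    ~risk_allele_freq, ~odds_ratio, ~coding_class, ~study_id,
    "1q24.3", "1", "CD", 1L, "rs1001", 0.30, 1.20, "noncoding", "S1",
    "1q24.3", "1", "CD", 2L, "rs1002", 0.05, 1.60, "missense_damaging", "S1",
    "16q12.1", "16", "CD", 1L, "rs2001", 0.25, 1.30, "pLOF", "S2")
}

toy_genes <- function() {
  tibble::tribble(
    ~locus_id, ~chrom, ~disease, ~gene, ~category, ~study_id,
    "1q24.3", "1", "CD", "FASLG", "pLOF_missense_damaging", "S1",
    "1q24.3", "1", "CD", "FASLG", "molecular_qtl_colocalization", "S3",
    "1q24.3", "1", "CD", "TNFSF18", "chromatin_interaction", "S4")
}

# variants table builder: one row per prioritized variant
variant_rows <- function(locus, disease, rank, method, ids,
                         coding = "noncoding", direction = "risk",
                         study = paste0("S_", locus, "_", disease)) {
  tibble::tibble(locus_id = locus, chrom = "1", disease = disease,
                 signal_rank = as.integer(rank), method_class = method,
                 variant_id = ids,
                 coding_class = rep_len(coding, length(ids)),
                 direction_of_effect = rep_len(direction, length(ids)),
                 study_id = study)
}

# 95% binomial CI check: is phat consistent with p at sample size n?
within_binom_ci <- function(phat, p, n) {
  abs(phat - p) <= 1.96 * sqrt(p * (1 - p) / n)
}
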