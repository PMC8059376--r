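#' Configuration for the founder-mosaic haplotype generator
#'
#' Founder haplotypes are drawn with site-wise allele frequencies uniform on
#' (0.05, 0.5); descendant haplotypes are mosaics of founders with crossover
#' points placed at per-base-pair rate `recomb_rate` between adjacent
#' variants, plus independent per-site mutation flips. The result is a
#' block-LD panel suitable for credible-set simulation.
#'
#' @param n_founders Number of founder haplotypes (>= 2).
#' @param n_haplotypes Panel size H.
#' @param n_variants Variants M.
#' @param region_length Region span in bp (default 100 kb).
#' @param recomb_rate Per-bp crossover probability between adjacent variants
#'   (default 3e-5, about 3 blocks per 100 kb).
#' @param mutation_rate Per-site allele-flip probability.
#' @param seed RNG seed.
#' @return A `hap_config` list.
#' @export
hap_config <- function(n_founders = 30, n_haplotypes = 2000,
                       n_variants = 150, region_length = 1e5,
                       recomb_rate = 3e-5, mutation_rate = 0.002,
                       seed = 1) {
  stopifnot(n_founders >= 2, n_haplotypes >= 4, n_variants >= 2,
            recomb_rate >= 0, recomb_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(n_founders = n_founders, n_haplotypes = n_haplotypes,
                 n_variants = n_variants, region_length = region_length,
                 recomb_rate = recomb_rate, mutation_rate = mutation_rate,
                 seed = seed),
            class = "hap_config")
}

#' Generate a block-LD haplotype panel
#'
#' @param config A [hap_config()].
#' @return A [haplotype_panel()]; fixed sites are dropped, so the panel can
#'   have fewer than `n_variants` columns. Seeded runs are bit-identical.
#' @export
sim_haplotypes <- function(config = hap_config()) {
  with_seed(config$seed, {
    m <- config$n_variants
    h <- config$n_haplotypes
    positions <- sort(sample.int(config$region_length, m))
    freqs <- runif(m, 0.05, 0.5)
    founders <- matrix(rbinom(config$n_founders * m, 1,
                              rep(freqs, each = config$n_founders)),
                       config$n_founders, m)
    gaps <- diff(positions)
    p_switch <- pmin(config$recomb_rate * gaps, 1)
    alleles <- matrix(0L, h, m)
    for (i in seq_len(h)) {
      switches <- c(0L, rbinom(m - 1, 1, p_switch))
      segment <- cumsum(switches) + 1L
      founder_per_segment <- sample.int(config$n_founders,
                                        max(segment), replace = TRUE)
      alleles[i, ] <- founders[cbind(founder_per_segment[segment],
                                     seq_len(m))]
    }
    if (config$mutation_rate > 0) {
      flips <- matrix(rbinom(h * m, 1, config$mutation_rate), h, m)
      alleles <- abs(alleles - flips)
    }
    f <- colMeans(alleles)
    keep <- f > 0 & f < 1
    if (!any(keep)) abort("generated panel has no segregating sites")
    haplotype_panel(alleles[, keep, drop = FALSE], positions[keep],
                    paste0("chr1:", positions[keep], ":A:G"),
                    ancestry = "synthetic founder mosaic")
  })
}
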