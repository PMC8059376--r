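#' Phased haplotype panel
#'
#' A panel holds an H x M matrix of 0/1 alleles (H haplotypes, M variants)
#' with strictly increasing 1-based base-pair positions and variant labels.
#' Panels are the basis for LD computation and summary-statistic simulation.
#'
#' @param alleles Integer/numeric H x M matrix with entries in `{0, 1}`.
#' @param positions Strictly increasing integer vector of length M.
#' @param variant_ids Character vector of length M (default `v1..vM`).
#' @param ancestry Free-text ancestry label.
#' @return A `haplotype_panel` object.
#' @export
haplotype_panel <- function(alleles, positions,
                            variant_ids = paste0("v", seq_len(ncol(alleles))),
                            ancestry = "synthetic") {
  alleles <- as.matrix(alleles)
  if (!all(alleles %in% c(0, 1))) {
    abort("haplotype alleles must all be 0 or 1")
  }
  if (nrow(alleles) < 4) {
    abort("a haplotype panel needs at least 4 haplotypes")
  }
  if (length(positions) != ncol(alleles) ||
      any(diff(positions) <= 0) || any(positions < 1)) {
    abort("positions must be 1-based, strictly increasing, one per variant")
  }
  if (length(variant_ids) != ncol(alleles)) {
    abort("variant_ids must have one label per variant")
  }
  storage.mode(alleles) <- "integer"
  structure(
    list(alleles = alleles, positions = as.integer(positions),
         variant_ids = as.character(variant_ids), ancestry = ancestry),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$alleles), " haplotypes x ",
      ncol(x$alleles), " variants (", x$ancestry, "), span ",
      min(x$positions), "-", max(x$positions), " bp\n", sep = "")
  invisible(x)
}

#' Per-variant alternate-allele frequencies of a panel
#'
#' @param panel A [haplotype_panel()].
#' @return Numeric vector of length M.
#' @export
allele_freq <- function(panel) {
  colMeans(panel$alleles)
}

#' Filter a panel to common variants
#'
#' Retains variants whose minor-allele frequency exceeds `threshold`
#' (strictly), preserving variant order. The conventional GWAS common-variant
#' filter is `MAF > 0.01`.
#'
#' @param panel A [haplotype_panel()].
#' @param threshold MAF threshold in `[0, 0.5)`.
#' @return The filtered `haplotype_panel`.
#' @export
maf_filter <- function(panel, threshold = 0.01) {
  if (threshold < 0 || threshold >= 0.5) {
    abort("threshold must lie in [0, 0.5)")
  }
  f <- allele_freq(panel)
  keep <- pmin(f, 1 - f) > threshold
  if (!any(keep)) {
    abort("MAF filter removed every variant in the panel")
  }
  haplotype_panel(panel$alleles[, keep, drop = FALSE],
                  panel$positions[keep], panel$variant_ids[keep],
                  panel$ancestry)
}

#' Signed LD correlation matrix of a panel
#'
#' Computes the M x M matrix of signed correlations
#' `r_ij = D_ij / sqrt(p_i (1 - p_i) p_j (1 - p_j))`, where `D_ij` is the
#' two-locus haplotype covariance. Equivalent to the Pearson correlation of
#' the 0/1 allele columns; the diagonal is exactly 1.
#'
#' @param panel A [haplotype_panel()] with no fixed variants.
#' @return An M x M symmetric correlation matrix with the panel's variant
#'   IDs as dimnames.
#' @export
compute_ld <- function(panel) {
  f <- allele_freq(panel)
  if (any(f == 0 | f == 1)) {
    abort("LD is undefined for fixed variants; apply maf_filter() first")
  }
  r <- cor(panel$alleles)
  diag(r) <- 1
  dimnames(r) <- list(panel$variant_ids, panel$variant_ids)
  r
}

#' Read a haplotype panel from a VCF or TSV haplotype matrix
#'
#' VCF input (requires the `vcfR` package) must carry phased `GT` fields;
#' each sample contributes two haplotypes. TSV input is a plain 0/1 matrix
#' with variants as columns, a header row of variant IDs, and an optional
#' leading comment line `#positions: p1,p2,...`; without one, positions
#' default to `1..M`.
#'
#' @param path Input file (`.vcf` or TSV).
#' @param ancestry Ancestry label to attach.
#' @return A [haplotype_panel()].
#' @export
read_haplotypes <- function(path, ancestry = basename(path)) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      abort("reading VCF panels requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v)
    if (any(grepl("/", gt, fixed = TRUE))) {
      abort("VCF genotypes must be phased (| separator)")
    }
    h1 <- apply(gt, 2, function(x) as.integer(substr(x, 1, 1)))
    h2 <- apply(gt, 2, function(x) as.integer(substr(x, 3, 3)))
    alleles <- t(cbind(h1, h2))
    fix <- vcfR::getFIX(v)
    ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                  paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
    haplotype_panel(alleles, as.integer(fix[, "POS"]), ids, ancestry)
  } else {
    lines <- readLines(path, warn = FALSE)
    pos <- NULL
    if (grepl("^#positions:", lines[1])) {
      pos <- as.integer(strsplit(sub("^#positions:\\s*", "", lines[1]),
                                 ",")[[1]])
      lines <- lines[-1]
    }
    tbl <- utils::read.delim(text = lines, check.names = FALSE)
    alleles <- as.matrix(tbl)
    haplotype_panel(alleles, pos %||% seq_len(ncol(alleles)),
                    colnames(alleles), ancestry)
  }
}
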