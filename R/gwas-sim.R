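#' Expected association Z-scores under a single causal variant
#'
#' Closed-form expectation of case-control GWAS Z-scores when one variant of
#' the panel drives the association. With population (control) risk-allele
#' frequency `f0` at the causal variant and per-allele odds ratio `psi`, the
#' case frequency is `f1 = psi * f0 / (1 + f0 * (psi - 1))`, the causal
#' expected Z is
#' `log(psi) / sqrt(1/(2 n1 f1 (1 - f1)) + 1/(2 n0 f0 (1 - f0)))`,
#' and every other variant's expectation is attenuated by its LD with the
#' causal variant: `E[Z_i] = r_ic * E[Z_c]`. The control frequency is
#' approximated by the panel frequency (rare-ish disease approximation).
#'
#' @param panel A [haplotype_panel()].
#' @param ld LD matrix from [compute_ld()].
#' @param causal_index Column index of the causal variant.
#' @param odds_ratio Per-allele odds ratio `psi > 0`.
#' @param n_cases,n_controls Case and control sample sizes.
#' @return Numeric vector of expected Z-scores, one per variant.
#' @export
expected_z <- function(panel, ld, causal_index, odds_ratio,
                       n_cases, n_controls) {
  if (odds_ratio <= 0) abort("odds_ratio must be positive")
  m <- ncol(panel$alleles)
  if (causal_index < 1 || causal_index > m) {
    abort("causal_index out of range")
  }
  f0 <- allele_freq(panel)[causal_index]
  f1 <- odds_ratio * f0 / (1 + f0 * (odds_ratio - 1))
  v_c <- 1 / (2 * n_cases * f1 * (1 - f1)) +
    1 / (2 * n_controls * f0 * (1 - f0))
  z_c <- log(odds_ratio) / sqrt(v_c)
  unname(ld[, causal_index] * z_c)
}

# per-variant sampling variance of log-OR under the null approximation
# (control frequency ~ population frequency in both arms)
sampling_variance <- function(panel, n_cases, n_controls) {
  f <- allele_freq(panel)
  1 / (2 * n_cases * f * (1 - f)) + 1 / (2 * n_controls * f * (1 - f))
}

# clip negative eigenvalues and renormalize to a correlation matrix;
# errors if the repair moves any entry by more than `max_shift`
repair_psd <- function(r, eps = 1e-10, max_shift = 0.01) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= eps) {
    return(list(r = r, factor = e$vectors %*% (sqrt(pmax(e$values, 0)) *
                                                 t(e$vectors))))
  }
  vals <- pmax(e$values, eps)
  r2 <- e$vectors %*% (vals * t(e$vectors))
  r2 <- stats::cov2cor(r2)
  shift <- max(abs(r2 - r))
  if (shift > max_shift) {
    abort(sprintf("LD matrix is too far from positive semidefinite (max repair shift %.3g)", shift))
  }
  warn(sprintf("LD matrix repaired to PSD (max entry shift %.3g)", shift))
  e2 <- eigen(r2, symmetric = TRUE)
  list(r = r2, factor = e2$vectors %*% (sqrt(pmax(e2$values, 0)) *
                                          t(e2$vectors)))
}

# draw an n_reps x M matrix of Z-scores ~ MVN(mu, r) given a factor A with
# A A' = r (rows of eps %*% t(A) have covariance r)
draw_z <- function(n_reps, mu, factor) {
  m <- length(mu)
  eps <- matrix(rnorm(n_reps * m), n_reps, m)
  sweep(eps %*% t(factor), 2, mu, "+")
}

#' Simulate case-control GWAS summary statistics
#'
#' Draws replicate Z-score vectors from a multivariate normal with mean
#' [expected_z()] and covariance equal to the LD matrix, then back-fills
#' effect sizes, standard errors and two-sided p-values. Each replicate is
#' one simulated association scan over the panel's variants. Runs with the
#' same seed are bit-identical.
#'
#' @inheritParams expected_z
#' @param n_reps Number of replicate scans.
#' @param seed RNG seed.
#' @return A tibble with columns `rep`, `variant_id`, `z`, `beta`, `se`,
#'   `p` (long format, `n_reps * M` rows).
#' @export
simulate_summary_stats <- function(panel, ld, causal_index, odds_ratio,
                                   n_cases, n_controls, n_reps = 1,
                                   seed = 1) {
  stopifnot(n_reps >= 1)
  mu <- expected_z(panel, ld, causal_index, odds_ratio, n_cases, n_controls)
  se <- sqrt(sampling_variance(panel, n_cases, n_controls))
  rep_ld <- repair_psd(ld)
  z <- with_seed(seed, draw_z(n_reps, mu, rep_ld$factor))
  m <- ncol(panel$alleles)
  tibble(
    rep = rep(seq_len(n_reps), each = m),
    variant_id = rep(panel$variant_ids, times = n_reps),
    z = as.vector(t(z)),
    beta = as.vector(t(z)) * rep(se, times = n_reps),
    se = rep(se, times = n_reps),
    p = pmax(2 * pnorm(-abs(as.vector(t(z)))), .Machine$double.xmin))
}
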