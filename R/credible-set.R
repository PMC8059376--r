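#' Prior settings for approximate-Bayes-factor fine-mapping
#'
#' @param prior_variance Prior variance `W` of the causal log-odds effect
#'   (default 0.04, i.e. effect-size SD 0.2 on the log-odds scale, the usual
#'   credible-set convention).
#' @param threshold Credible-set mass threshold in `(0, 1]` (default 0.95).
#' @return An `abf_params` list.
#' @export
abf_params <- function(prior_variance = 0.04, threshold = 0.95) {
  stopifnot(prior_variance > 0, threshold > 0, threshold <= 1)
  structure(list(prior_variance = prior_variance, threshold = threshold),
            class = "abf_params")
}

#' Wakefield approximate Bayes factor
#'
#' Evidence for an effect versus no effect at one variant, from its Z-score
#' and sampling variance. With shrinkage `r = W / (W + V)`:
#' `ABF = sqrt(1 - r) * exp(z^2 * r / 2)` (alternative over null).
#'
#' @param z Association Z-score(s).
#' @param V Sampling variance(s) of the effect estimate, `> 0`.
#' @param params An [abf_params()].
#' @param log Return the log Bayes factor?
#' @return Numeric vector of (log) Bayes factors.
#' @export
wakefield_abf <- function(z, V, params = abf_params(), log = FALSE) {
  if (any(V <= 0)) abort("sampling variance V must be positive")
  r <- params$prior_variance / (params$prior_variance + V)
  labf <- 0.5 * log1p(-r) + z^2 * r / 2
  if (log) labf else exp(labf)
}

#' Posterior inclusion probabilities under a single causal variant
#'
#' Normalises per-variant Wakefield Bayes factors under equal causal priors:
#' `PIP_i = ABF_i / sum_j ABF_j`. Computed in log space (log-sum-exp) so
#' large Z-scores cannot overflow.
#'
#' @param z Vector of Z-scores (or a summary-statistics tibble with columns
#'   `z` and `se`, one scan).
#' @param se Vector of standard errors (sampling variance is `se^2`).
#' @param params An [abf_params()].
#' @return Numeric vector of PIPs summing to 1.
#' @export
finemap_pips <- function(z, se = NULL, params = abf_params()) {
  if (is.data.frame(z)) {
    se <- z$se
    z <- z$z
  }
  if (length(z) < 1) abort("at least one variant is required")
  if (any(se <= 0)) abort("all standard errors must be positive")
  labf <- wakefield_abf(z, se^2, params, log = TRUE)
  mx <- max(labf)
  w <- exp(labf - mx)
  w / sum(w)
}

#' Build a credible set from posterior inclusion probabilities
#'
#' Sorts variants by descending PIP (ties broken by ascending index) and
#' takes the minimal prefix whose cumulative posterior reaches the mass
#' threshold.
#'
#' @param pips Vector of PIPs summing to 1 (tolerance 1e-8).
#' @param params An [abf_params()]; only the threshold is used.
#' @param z Optional Z-score vector used to record the lead variant
#'   (largest `|z|`).
#' @return A `credible_set` list: `members` (indices, descending PIP),
#'   `pips`, `mass`, `size`, and `lead_index` when `z` is supplied.
#' @export
credible_set <- function(pips, params = abf_params(), z = NULL) {
  if (abs(sum(pips) - 1) > 1e-8) {
    abort("pips must sum to 1 (within 1e-8)")
  }
  ord <- order(-pips, seq_along(pips))
  cum <- cumsum(pips[ord])
  size <- which(cum >= params$threshold - 1e-12)[1]
  if (is.na(size)) size <- length(pips)
  structure(
    list(members = ord[seq_len(size)], pips = pips, mass = cum[size],
         size = size,
         lead_index = if (!is.null(z)) which.max(abs(z)) else NA_integer_),
    class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat("<credible_set> ", x$size, " variant(s), mass ",
      formatC(x$mass, digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.credible_set <- function(x, ...) {
  tibble(variant_index = x$members,
         pip = x$pips[x$members],
         cumulative_mass = cumsum(x$pips[x$members]))
}

# one simulated scan -> credible-set statistics, given precomputed pieces
credset_stats_one <- function(z, se, causal, params, lead_ties = "random") {
  pips <- finemap_pips(z, se, params)
  cs <- credible_set(pips, params)
  az <- abs(z)
  leads <- which(az == max(az))
  lead <- if (length(leads) > 1 && lead_ties == "random") {
    leads[sample.int(length(leads), 1)]
  } else {
    leads[1]
  }
  c(size = cs$size,
    causal_in_set = causal %in% cs$members,
    lead_is_causal = lead == causal)
}

#' Credible-set simulation experiment over a scenario grid
#'
#' For each scenario (odds ratio x sample size), simulates `n_reps`
#' association scans on the panel, fine-maps each with Wakefield ABFs, and
#' records the credible-set size, whether the causal variant is inside the
#' set, and whether the lead variant (largest `|Z|`) is the causal variant.
#'
#' @param panel A [haplotype_panel()] (apply [maf_filter()] first).
#' @param grid Tibble of scenarios with columns `odds_ratio`, `n_cases`,
#'   `n_controls`.
#' @param params An [abf_params()].
#' @param n_reps Replicates per scenario.
#' @param causal Causal-variant policy: a fixed variant index; `"credset"`
#'   (default) mimics assigning a randomly chosen member of the credible set
#'   of a reference scan as the causal variant, per scenario; or
#'   `"uniform_each"`, a fresh uniform draw over variants in every replicate.
#' @param effect `"fixed"` uses each scenario's `odds_ratio`; `"prior"`
#'   draws the log odds ratio from `N(0, W)` per replicate (the
#'   well-specified Bayesian setting used for calibration checks).
#' @param seed RNG seed; runs are bit-reproducible.
#' @param lead_ties `"random"` (default) or `"first"` for deterministic
#'   lowest-index tie-breaking of the lead variant.
#' @return A `credset_experiment` object with `$replicates` (per-replicate
#'   tibble) and `$summary` (per-scenario median/IQR set size, % lead ==
#'   causal, % causal in set). `tidy()` returns the summary, `glance()` the
#'   experiment dimensions, `autoplot()` the scenario trends.
#' @export
run_credset_experiment <- function(panel, grid, params = abf_params(),
                                   n_reps = 1000, causal = "credset",
                                   effect = c("fixed", "prior"), seed = 1,
                                   lead_ties = c("random", "first")) {
  effect <- arg_match(effect)
  lead_ties <- arg_match(lead_ties)
  ld <- compute_ld(panel)
  rep_ld <- repair_psd(ld)
  m <- ncol(panel$alleles)
  w_sd <- sqrt(params$prior_variance)
  f <- allele_freq(panel)

  reps <- with_seed(seed, purrr::map_dfr(seq_len(nrow(grid)), function(s) {
    sc <- grid[s, ]
    se <- sqrt(sampling_variance(panel, sc$n_cases, sc$n_controls))
    z_c <- function(idx, psi) {
      expected_z(panel, ld, idx, psi, sc$n_cases, sc$n_controls)
    }
    causal_fixed <- NULL
    if (is.numeric(causal)) {
      causal_fixed <- as.integer(causal)
    } else if (causal == "credset") {
      # reference scan: provisional uniform causal, one simulated scan,
      # then a uniform draw over its credible-set members
      prov <- sample.int(m, 1)
      psi0 <- if (effect == "prior") exp(rnorm(1, 0, w_sd)) else sc$odds_ratio
      z0 <- drop(draw_z(1, z_c(prov, psi0), rep_ld$factor))
      cs0 <- credible_set(finemap_pips(z0, se, params), params)
      causal_fixed <- cs0$members[sample.int(length(cs0$members), 1)]
    }
    eps <- draw_z(n_reps, rep(0, m), rep_ld$factor)
    out <- matrix(NA_real_, n_reps, 3)
    causal_idx <- integer(n_reps)
    for (i in seq_len(n_reps)) {
      ci <- causal_fixed %||% sample.int(m, 1)
      psi <- if (effect == "prior") exp(rnorm(1, 0, w_sd)) else sc$odds_ratio
      z <- z_c(ci, psi) + eps[i, ]
      out[i, ] <- credset_stats_one(z, se, ci, params, lead_ties)
      causal_idx[i] <- ci
    }
    tibble(scenario = s, odds_ratio = sc$odds_ratio,
           n_cases = sc$n_cases, n_controls = sc$n_controls,
           rep = seq_len(n_reps), causal_index = causal_idx,
           set_size = as.integer(out[, 1]),
           causal_in_set = as.logical(out[, 2]),
           lead_is_causal = as.logical(out[, 3]))
  }))

  summary <- reps %>%
    group_by(.data$scenario, .data$odds_ratio, .data$n_cases,
             .data$n_controls) %>%
    summarise(
      n_reps = n(),
      median_set_size = median(.data$set_size),
      q25_set_size = quantile(.data$set_size, 0.25),
      q75_set_size = quantile(.data$set_size, 0.75),
      pct_lead_is_causal = 100 * mean(.data$lead_is_causal),
      pct_causal_in_set = 100 * mean(.data$causal_in_set),
      .groups = "drop")

  structure(
    list(replicates = reps, summary = summary, params = params,
         causal = causal, effect = effect, seed = seed,
         n_variants = m),
    class = "credset_experiment")
}

#' @export
print.credset_experiment <- function(x, ...) {
  cat("<credset_experiment> ", nrow(x$summary), " scenario(s), ",
      x$summary$n_reps[1], " replicates, ", x$n_variants, " variants\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.credset_experiment <- function(x, ...) {
  x$summary
}

#' @export
glance.credset_experiment <- function(x, ...) {
  tibble(n_scenarios = nrow(x$summary), n_reps = x$summary$n_reps[1],
         n_variants = x$n_variants,
         prior_variance = x$params$prior_variance,
         threshold = x$params$threshold, effect = x$effect)
}

#' @describeIn run_credset_experiment Plot median credible-set size and %
#'   lead-is-causal against the odds ratio, one line per sample size.
#' @param x A `credset_experiment`.
#' @param ... Unused.
#' @export
autoplot.credset_experiment <- function(x, ...) {
  df <- x$summary %>%
    mutate(n_total = .data$n_cases + .data$n_controls) %>%
    tidyr::pivot_longer(c("median_set_size", "pct_lead_is_causal"),
                        names_to = "metric", values_to = "value") %>%
    mutate(metric = dplyr::recode(.data$metric,
                                  median_set_size = "median credible-set size",
                                  pct_lead_is_causal = "% lead == causal"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$odds_ratio),
                                   y = .data$value,
                                   colour = factor(.data$n_total),
                                   group = factor(.data$n_total))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "odds ratio", y = NULL, colour = "total n") +
    ggplot2::theme_minimal()
}
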