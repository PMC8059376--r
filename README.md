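# finecat

Credible-set simulation and evidence synthesis for autoimmune GWAS
fine-mapping.

GWAS loci pinpoint genomic regions, not causal variants or genes: linkage
disequilibrium (LD) spreads an association signal over many correlated
variants, and most hits are non-coding. Fine-mapping studies attack this
with statistical credible sets, functional experiments and integrative
algorithms, and a synthesis of their published results has to answer
questions such as: how often does a locus carry several independent
signals (allelic heterogeneity)? Do diseases sharing a locus share the
prioritized variants, and do the shared variants act in the same
direction? And across seven families of gene-prioritization evidence,
which gene in each locus is the consistently supported one?

finecat is an R package, tidyverse-shaped (tibbles in, tibbles out,
`tidy()`/`glance()`/`autoplot()` methods on result objects), for analysts
who compile or evaluate such fine-mapping syntheses. It implements:

* **Summary-statistic simulation under LD** — replicate case-control
  Z-score scans drawn from a multivariate normal with mean
  `E[Z_i] = r_ic * log(psi) / sqrt(1/(2 n1 f1 (1-f1)) + 1/(2 n0 f0 (1-f0)))`
  (with `f1` the case frequency implied by odds ratio `psi`) and
  covariance equal to the haplotype LD matrix.
* **Wakefield credible sets** — approximate Bayes factors
  `ABF = sqrt(1-r) * exp(z^2 r / 2)`, `r = W/(W+V)`, posterior inclusion
  probabilities, minimal 95% credible sets, and a scenario-grid
  experiment (credible-set size and lead-variant accuracy versus odds
  ratio, sample size).
* **Catalog statistics** — allelic-heterogeneity counts, Welch's t
  comparison of additional versus lead signals (MAF and odds ratio),
  prioritization summaries, allele-frequency classes, and
  agonist/antagonist therapeutic-direction calls.
* **Cross-disease comparisons** — prioritized-variant overlap at shared
  loci and direction-of-effect concordance with one representative
  variant per independent signal.
* **Gene confidence scores** — weighted evidence scores
  `E_g = sum_i w_i e_i` over seven evidence categories and
  locus-adjusted confidence scores `CS_gl = E_g - max(E_g' : g' != g)`,
  per-disease or disease-agnostic.
* **Synthetic data with ground truth** — a founder-mosaic haplotype
  generator, a catalog generator with planted true genes, multi-signal
  loci, shared variants and direction flips, and templated abstracts for
  the two-stage literature screen.

## Worked example

```r
library(finecat)

# a synthetic catalog of 40 loci with known ground truth
cat <- sim_catalog(catalog_config(n_loci = 40, seed = 42))

sum(multi_signal_loci(cat$signals)$multi_signal)
#> [1] 12

lead_vs_additional(cat$signals)
#> # A tibble: 2 × 8
#>   metric mean_additional mean_lead n_additional n_lead t_statistic   dof p_value
#>   <chr>            <dbl>     <dbl>        <int>  <int>       <dbl> <dbl>   <dbl>
#> 1 maf             0.1000     0.249           25     24       -5.99  39.1 5.24e-7
#> 2 odds_…          1.60       1.26            25     24        7.63  37.7 3.72e-9

glance(variant_overlap(cat$variants))
#> # A tibble: 1 × 4
#>   n_pairs n_comparisons pair_overlap_fraction locus_overlap_fraction
#>     <int>         <int>                 <dbl>                  <dbl>
#> 1      27            40                 0.481                    0.4

glance(direction_concordance(cat$variants))
#> # A tibble: 1 × 4
#>   n_pairs n_assessed n_unassessed pct_concordant
#>     <int>      <int>        <int>          <dbl>
#> 1      13         16            0           81.2

rank_genes(score_genes(cat$genes, mode = "disease_agnostic"), 5)[, c(1, 3, 6, 7)]
#>   locus_id gene         E    CS
#> 1 18q11.3  GENE018A     9     9
#> 2 17q11.2  GENE017A     9     8
#> 3 16q12.2  GENE038A     9     8
#> 4 6q11.3   GENE006A     9     7
#> 5 8q11.2   GENE008A     9     7
```

At 40 loci the catalog realises its planted rates: 12/40 multi-signal
loci (planted probability 0.22), additional signals rarer
(mean MAF 0.10 vs 0.25) and larger-effect (mean OR 1.60 vs 1.26) than
leads with a Welch p of 5.2e-7, variant overlap at 40% of cross-disease
locus comparisons, 81% direction concordance, and every top-confidence
gene (`CS > 0`) is its locus's planted true gene.

The simulation arm works the same way:

```r
panel <- maf_filter(sim_haplotypes(hap_config(seed = 1)), 0.01)  # 2000 x ~150
grid <- tibble::tibble(odds_ratio = c(1.1, 1.3),
                       n_cases = 25000, n_controls = 25000)
ex <- run_credset_experiment(panel, grid, n_reps = 200, causal = 42, seed = 9)
tidy(ex)[, c("odds_ratio", "median_set_size", "pct_lead_is_causal",
             "pct_causal_in_set")]
#>   odds_ratio median_set_size pct_lead_is_causal pct_causal_in_set
#> 1        1.1               1                100               100
#> 2        1.3               1                100               100
autoplot(ex)
```

A well-powered scan on this panel resolves the planted causal variant to
a single-variant credible set; smaller samples and odds ratios broaden
the sets and erode lead-variant accuracy (see the scenario grid in the
acceptance script and the methods vignette).

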