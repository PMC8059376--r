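---
title: "Methods: credible-set simulation and evidence synthesis for autoimmune GWAS fine-mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: credible-set simulation and evidence synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finecat)
library(dplyr)
```

finecat implements the analytical machinery of a systematic synthesis of
GWAS fine-mapping evidence in autoimmune disease. It has four arms: a
credible-set simulation experiment on haplotype panels, descriptive and
inferential statistics over curated fine-mapping catalogs, cross-disease
overlap and concordance comparisons, and a weighted evidence-integration
framework that assigns confidence scores to candidate trait-relevant genes.
A synthetic-data module generates every input with known ground truth, so
the whole pipeline is testable offline.

This vignette records the models, the tunable parameters, the numerical
choices, and the points where a design was genuinely open and a choice had
to be made.

## Simulation of summary statistics under LD

A haplotype panel is an $H \times M$ matrix of phased 0/1 alleles. LD is
the signed correlation of allele columns,
$r_{ij} = D_{ij} / \sqrt{p_i(1-p_i)\,p_j(1-p_j)}$, with $D_{ij}$ the
two-locus haplotype covariance; `compute_ld()` is tested against a naive
counting implementation.

`simulate_summary_stats()` works at the summary-statistic level rather
than simulating individual genotypes and phenotypes: replicate Z-score
vectors are drawn from a multivariate normal whose mean is the closed-form
expectation under a single causal variant and whose covariance is the LD
matrix. With control (= panel) risk-allele frequency $f_0$ at the causal
variant and per-allele odds ratio $\psi$, the case frequency is

$$f_1 = \frac{\psi f_0}{1 + f_0(\psi - 1)},$$

the causal expected Z is

$$\mathbb{E}[Z_c] = \frac{\log\psi}
{\sqrt{\tfrac{1}{2 n_1 f_1 (1-f_1)} + \tfrac{1}{2 n_0 f_0 (1-f_0)}}},$$

and every other variant is attenuated by its LD with the causal variant,
$\mathbb{E}[Z_i] = r_{ic}\,\mathbb{E}[Z_c]$. Two approximations are part
of the contract and the tests are exact against them: the control
frequency stands in for the population frequency (reasonable for
uncommon diseases), and per-variant standard errors are computed at the
null (panel frequency in both arms), so `beta = z * se` is a back-filled
effect estimate rather than a likelihood quantity.

Numerical notes:

* Empirical correlation matrices of haplotype data are positive
  semidefinite up to round-off, but duplicated columns make them exactly
  singular. Before sampling, eigenvalues below $10^{-10}$ are clipped and
  the matrix renormalised to unit diagonal; if that repair moves any entry
  by more than 0.01 the matrix is rejected with an error rather than
  silently distorted.
* One scenario seed drives all replicates; draws are consumed in a fixed
  order, so runs are bit-reproducible.

## Credible sets

Fine-mapping uses the standard single-causal-variant approximate Bayes
factor. With shrinkage $r = W/(W+V)$, where $V$ is the sampling variance
of the effect estimate and $W$ the prior variance of the causal log-odds
effect,

$$\mathrm{ABF} = \sqrt{1-r}\; e^{z^2 r / 2}$$

(evidence for an effect over none). Posterior inclusion probabilities
normalise the ABFs under equal priors; the computation is done in log
space with log-sum-exp, since $z^2/2$ overflows `exp()` well inside the
range of real GWAS hits. The 95% credible set is the minimal
descending-PIP prefix reaching the mass threshold; exact PIP ties are
broken by ascending variant index so sets are deterministic.

Defaults, all configurable through `abf_params()`:

| parameter | default | meaning |
|---|---|---|
| `prior_variance` (W) | 0.04 | prior variance of the causal log-OR (SD 0.2), the usual credible-set convention |
| `threshold` | 0.95 | credible-set mass |
| MAF filter | 0.01 | common-variant threshold applied to panels |

`run_credset_experiment()` runs a scenario grid (odds ratio × sample
size) and records, per replicate, the credible-set size, whether the lead
variant (largest |Z|; exact ties broken at random, or by lowest index in
`lead_ties = "first"` mode) is the causal variant, and whether the causal
variant is inside the set. Three causal-variant policies exist because the
two headline analyses need different ones:

* `causal = <index>`: fixed, for scenario grids where comparability across
  cells matters.
* `causal = "credset"`: a seeded uniform draw over the credible-set
  members of a reference scan, mimicking how a "true" causal variant is
  assigned when simulating from a real associated locus.
* `causal = "uniform_each"`: a fresh uniform draw per replicate. Combined
  with `effect = "prior"` (log-OR drawn from $N(0, W)$ per replicate)
  this is the well-specified Bayesian setting in which 95% credible sets
  should cover the causal variant in 95% of replicates; the calibration
  test asserts ≥ 93%, nominal minus Monte-Carlo slack at 1,000
  replicates.

The calibration argument only holds when the generative model matches the
prior — fixed-$\psi$ grids are *not* expected to be exactly calibrated,
which is why the calibration experiment draws effects from the prior while
the trend experiment fixes them.

## Catalog statistics

Catalogs are plain tibbles with fixed TSV schemas (`read_catalog()` /
`write_catalog()` / `validate_catalog()`). Conventions that required a
decision:

* Allele-frequency classes fold frequencies at 0.5 and use closed upper
  bounds: common > 0.1, low (0.01, 0.1], rare ≤ 0.01. The conventional
  class definitions leave the exact boundary values unassigned; assigning
  boundaries downward is arbitrary but documented and total.
* A locus has allelic heterogeneity when *any* study reports ≥ 2
  independent signals for it, with the per-locus count being the maximum
  over per-study, per-disease reports.
* `lead_vs_additional()` compares additional (rank ≥ 2) against lead
  signals at multi-signal loci with Welch's unequal-variance t test
  (delegated to `stats::t.test`; tests verify it against a textbook
  implementation of the Welch statistic and Welch–Satterthwaite degrees
  of freedom). The HLA locus (6p21.32) is excluded by default — its
  haplotype-level reporting is not comparable — and repeated reports of
  the same (locus, disease, rank) are deduplicated keeping the
  first-listed study, since pooling duplicate reports would pseudo-
  replicate signals.
* Prioritization counts are per locus-by-disease signal, not per study; a
  signal is coding-damaging when any prioritized variant is pLOF or
  predicted-damaging missense.

## Cross-disease comparisons

For each unordered disease pair and each locus fine-mapped for both,
overlap is non-empty intersection of the prioritized-variant sets
(partial overlap counts). Two global fractions are reported: the fraction
of pairs with at least one overlapping locus, and the fraction of
individual (pair, locus) comparisons that overlap. The latter is the
quantity the synthetic generator plants per locus, so it is the one that
recovery tests and the acceptance script compare against the planted
rate.

Direction concordance selects one representative shared variant per
independent signal — the lowest genomic position, deterministically, with
variant-ID order breaking ties for rsIDs without coordinates — and asks
whether the same allele is the risk allele for both diseases. Variants
missing a direction are tallied as unassessed, never guessed.

## Gene confidence scores

For gene $g$ in a locus context, the weighted total evidence score is

$$E_g = \sum_{i=1}^{7} w_i\, e_i,$$

with $e_i \in \{0,1\}$ indicating presence of at least one record in
evidence category $i$ (duplicates never double-count), and the confidence
score adjusts for the best competing gene in the locus:

$$CS_{gl} = E_g - \max_{g' \in S,\, g' \neq g} E_{g'},$$

with the empty maximum defined as 0. Consequences, all tested: at most
one gene per locus context has $CS > 0$; a top tie gives all tied genes
$CS = 0$; in a two-gene locus $CS_A = -CS_B$; scaling all weights scales
every score and preserves rankings.

The seven categories are pLOF/missense-damaging variants, gene-based
(rare-variant) association, molecular-QTL colocalization, chromatin
interaction, experimental follow-up, network/co-expression, and
integrative algorithms. The first two carry weight 2 and the rest 1 by
default: direct coding evidence and gene-level association are the most
direct ways a gene can be implicated, and the constructor enforces that
ordering for any user-supplied weights. Per-disease mode scores each
(locus, disease) separately; disease-agnostic mode pools evidence across
all diseases with a signal at the locus, which can only add categories —
so agnostic $E_g \geq$ per-disease $E_g$, another tested invariant.

`strategy_overlap()` reports, for every category pair, the frequency of
at least one shared prioritized gene over co-dissected units, masking
pairs with fewer than five shared units (too noisy to display).

## The synthetic-data generators

`sim_haplotypes()` uses a founder-mosaic model: founders drawn with
site-wise allele frequencies uniform on (0.05, 0.5), descendants pasted
together from founder segments with crossover points at a per-bp rate,
plus rare mutation flips. This produces the block-LD structure that
credible-set behaviour depends on without needing a coalescent simulator.
It does *not* reproduce human demography, recombination hotspot maps, or
allele-frequency spectra, so absolute numbers from this panel (e.g. the
percentage of simulations whose lead variant is causal) characterise the
synthetic panel, not any particular 1000 Genomes population — real
African-ancestry panels carry more low-LD structure and give noticeably
lower lead-variant accuracy in the literature. The monotone trends in
odds ratio and sample size, and the calibration property, are the
transferable results.

`sim_catalog()` plants a known structure: each locus carries one true
gene among `genes_per_locus` candidates and is fine-mapped for exactly
two diseases (making per-locus overlap and flip indicators directly
identifiable); allelic heterogeneity, shared variants, direction flips
and coding-damaging signals are independent Bernoulli draws; the true
gene emits evidence per category with probability `category_sensitivity`
and decoys with `category_noise`. Variant IDs within a locus are drawn
without replacement so cross-disease overlap occurs only when planted.
The per-combination count of statistically prioritized variants is
$1 + \mathrm{Poisson}(7)$, split across the combination's signals.

The generator defaults are the study conditions of the catalog this
package models: 22% multi-signal loci; additional signals with mean MAF
0.09 and mean OR 1.52 against 0.25 and 1.26 for leads (Beta-distributed
MAFs and log-normal ORs with those means); median 8 statistical
variants; 11.5% coding-damaging signals; shared prioritized variants at
41% of cross-disease comparisons with 20.5% direction flips. They were
fixed once, from the catalog's reported statistics, and are not adjusted
per analysis.

`sim_abstracts()` emits templated abstracts that pass the two-stage
screen (GWAS + mechanism terms, then autoimmune-disease terms) at planted
rates. Screening matches case-insensitively on word-token boundaries;
"mechanism" and "mechanisms" are distinct tokens and both are configured,
and hyphenated compounds like "genome-wide" stay single tokens. Titles
are not searched by default. Synthetic abstracts exercise the matching
logic, not the ambiguity of real scientific prose, so passing screens here
says nothing about recall on a live literature corpus.

## Problem sizes

The test suite and the acceptance script use sizes chosen to make
Monte-Carlo checks decisive while keeping a full run on one CPU in a few
minutes: catalogs of 300 loci for headline statistics (550 where ≥ 200
planted shared-variant events are needed for a tight binomial interval),
a 2,000-haplotype × 150-variant panel, 500 replicates per scenario cell
for the trend grid and 1,000 for calibration and the best-case scenario,
and 10 generator seeds for the gene-recovery experiment. Stochastic
checks use binomial 95% confidence intervals around planted parameters
rather than point equality.

## Known limitations

* Single-causal-variant fine-mapping only; no stochastic-search or
  conditional multi-signal credible sets, and no colocalization across
  diseases.
* Allelic-heterogeneity discovery from raw genotypes (conditional,
  haplotype or Bayesian) is out of scope: the catalog statistics operate
  on *compiled* published signals.
* Strand-ambiguous (A/T, C/G) allele harmonization is not attempted;
  directions are taken as reported for the stated allele.
* The evidence weights are a two-level consensus ordering, not estimated
  quantities; rankings are robust to rescaling but not to re-ordering the
  weights.
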