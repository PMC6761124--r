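---
title: "Quantifying epigenetic drift in single-cell multi-omics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epigenetic drift in single-cell multi-omics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdrift)
library(data.table)
```

# The problem

Ageing tissues accumulate stochastic, cell-to-cell uncoordinated DNA
methylation changes — epigenetic drift — alongside coordinated shifts in
mean methylation. Parallel single-cell methylome and transcriptome
(scM&T-seq) experiments make it possible to ask, in the same cells,
whether this epigenomic disorder is mirrored by transcriptional
variability. scdrift implements the statistical machinery for that
question: a region-level cell-to-cell methylation heterogeneity score and
its normalisation, transcriptional variability statistics, an epigenetic
age predictor operating on aggregated single cells, and the per-cell
links between the two molecular layers — together with synthetic-data
generators so every stage can be exercised and validated without access
to sequencing data.

# The heterogeneity score

For one genomic region, let `r` be the cells × CpG-sites matrix of binary
methylation states (missing where a cell has no coverage). For every pair
of cells `c`, restricted to the `k` sites covered in both:

* `D_c` — the normalised Hamming distance, i.e. the fraction of shared
  sites at which the two cells disagree;
* `S_c` — the joint Shannon entropy (bits) of the ordered state-pair
  pattern over the four outcomes `(0,0), (0,1), (1,0), (1,1)`, with
  `0·log2(0) := 0`; it measures the complexity of the pairwise pattern
  and is at most 2;
* `w_c = k` — the pair's weight, its shared covered-CpG count.

The region score is the product of the two coverage-weighted means:

$$H(r) = \frac{\sum_c w_c D_c}{\sum_c w_c} \times
         \frac{\sum_c w_c S_c}{\sum_c w_c} \in [0, 2].$$

Pairs sharing fewer than 4 CpGs are not considered. `H` is zero whenever
all shared patterns agree, grows with stochastic cell-to-cell disorder,
is unaffected by permuting cells or sites, and tolerates missing data
because each pair is evaluated only on its shared sites. The Hamming term
alone would reward any disagreement, including a clean two-subpopulation
split; multiplying by the pairwise entropy emphasises disordered,
pattern-rich disagreement over structured ones.

```{r score-example}
m <- RegionCallMatrix("demo", rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))
region_heterogeneity(m)$H   # fully alternating pair: D = 1, S = 1, H = 1
```

## Normalisation and age contrasts

Raw `H` depends on a region's methylation level (it vanishes near 0% or
100% methylation), so scores are normalised by the distance to a rolling
median of `H` ordered by the region's coverage-weighted mean methylation
(`normalise_heterogeneity()`; window 1000 observations at genome scale,
proportionally smaller in the desk-scale examples below; regions below
0.05 or above 0.9 mean methylation are excluded first). Young/old
differences of the normalised score are then Z-scored in a sliding window
of 100 observations (`delta_het_zscore()`).

Two window-design choices deserve explanation:

* **Edge handling.** Rolling windows are centred and truncated at the
  ends of the ordering (an edge record keeps its full one-sided
  neighbourhood) rather than shrinking symmetrically; symmetric shrinkage
  would make the edge estimates degenerate on a handful of records.
* **Window ordering for the Z-score.** The young/old difference windows
  are ordered by the mean *methylation level* of the two ages (the same
  covariate the rolling-median normalisation conditions on), not by the
  heterogeneity values themselves. Ordering by the scored quantity would
  place genuinely shifted regions next to each other, so the local window
  mean would track — and subtract — the very signal being measured;
  ordering by an independent covariate preserves coordinated shifts while
  still standardising against regions of comparable methylation. The
  alternative ordering remains available via `order_by = "H_norm"`.

Before any scoring, regions with unreliable estimates are excluded
(`filter_regions()`): fewer than 20 CpG sites, fewer than 2 CpGs covered
per cell on average, or fewer than 100 pairwise comparisons in either
age, plus regions whose two ages differ by more than 10 in mean CpGs per
cell or by more than 200 pairwise comparisons.

# Transcriptional variability

Expression is normalised to reads per million of reads mapped to the
transcriptome (`normalise_rpm()`). A gene's variability is its *distance
to the median* (DM): `log2` of the squared coefficient of variation minus
a rolling average (window 100 genes) of that quantity over genes ordered
by mean expression, restricted to genes with mean RPM of at least 10
(`distance_to_median()`). DM is an expression-level-adjusted variability
measure: by construction it is nearly uncorrelated with the mean, and it
is invariant to global rescaling of sequencing depth. The rolling fit is
taken on the log scale because the right tail of CV² is heavy; a
parametric fit is deliberately avoided in favour of the windowed trend.

Companion statistics: expression frequency per age group with the
greater-than-15% young-to-old drop flag (`expression_frequency()`),
top-N variable genes by DM with deterministic tie-breaking
(`top_variable_genes()`), within-individual cell–cell Spearman
correlations including random 10-cell cohorts (1000 iterations,
`cell_correlation_analysis()`), and the similarity-to-young ranking:
each old cell's Spearman correlation with the per-gene mean of
`log2(RPM + 1)` across young cells, excluding genes expressed in fewer
than five cells, followed by per-gene correlation with that similarity
score and the top-200 lists in each direction (`similarity_to_young()`).
The `log2(x + 1)` transform is the field default; Spearman statistics are
insensitive to the choice.

# The epigenetic clock

Single-cell bisulfite coverage is too sparse for per-cell age
prediction, so cells are aggregated per individual by summing methylation
calls (`pseudobulk()`). The CpG panel is selected in three stages
(`select_sites()`): sites present in at least 70% of the training
samples; sites covered at least 5× in every target pseudobulk; and
finally training samples lacking any panel site are dropped. Methylation
values are binned to the nearest multiple of 20% — ties round up — so
that no read-depth information leaks into the methylation values
(`bin_methylation()`), and age in weeks is fitted by an elastic-net
linear model with the mixing parameter chosen over a small grid and the
penalty by 10-fold cross-validation, fold assignment fixed by a seed
(`fit_clock()`). The penalty family and fold count are conventional
choices for methylation clocks; both are arguments.

Prediction uncertainty due to cell composition is quantified by
cell-drop permutations (`permutation_ages()`): each of 100 permutations
removes a random 5% of the cells (round half up, at least one),
re-aggregates, and predicts — but only permutations in which every panel
site retains at least 4× coverage are kept.

# Synthetic data: what it emulates, and what it does not

`simulate_region()` draws one region as a template/stochastic mixture: a
shared template state per site (Bernoulli with the region's mean
methylation), each cell×site entry resampled independently with
probability `het_level`, then masked missing at random. This was chosen
over, say, a beta-binomial because it maps `het_level` monotonically onto
expected pairwise disagreement while holding mean methylation fixed —
exactly the two axes the normalisation machinery assumes are separable.
Defaults mirror the analysed study's scale: 35 cells per individual,
~30 CpGs per ~2 kb region, 50% global methylation, 50% missingness.
`simulate_cohorts()` arranges such regions into young/old per-individual
methylomes with class-wise shifts (e.g. LINE-1-like classes gaining
methylation and losing heterogeneity, Polycomb-target-like classes
gaining heterogeneity).

`simulate_expression()` draws negative-binomial counts on a log-spaced
mean grid with per-gene overdispersion, thinned by a Bernoulli detection
step logistic in the log mean — the standard mean–variance and dropout
structure of full-length scRNA-seq. `simulate_clock_data()` produces
pseudo-bulk training profiles whose causal sites drift linearly with age
(default 50 of 500 sites at ±0.015 methylation/week over ages 2–40
weeks, site noise s.d. 0.02, binomial sampling at 20× depth).

These generators reproduce the *statistical structure* the methods rely
on, not real data: no genomic autocorrelation between neighbouring
regions, no bisulfite conversion errors, no cell-cycle or batch
structure, no linked identity between the methylome and transcriptome of
an individual cell. Passing tests therefore demonstrate that the
implementation computes its statistics correctly and that the pipeline
recovers planted effects of realistic size — not that any biological
claim holds in real tissue.

# Numerical choices and degenerate inputs

* Binarisation of fractional per-cell CpG calls: methylated fraction
  ≥ 0.5 → 1 (round half up); the choice only matters for multi-read
  sites, which are rare in single-cell data. Strand merging of
  `pos`/`pos+1` call pairs is available but off by default (inputs are
  assumed pre-collapsed).
* Coverage files are 1-based; BED regions 0-based half-open; conversion
  happens once, inside `build_region_matrix()`.
* A zero-variance Z-score window yields z = 0; zero-variance genes get
  `dm = NA`; a region with no qualifying cell pair has undefined `H` and
  is skipped rather than scored 0.
* Down-sampling to equal depth treats each counted read at each CpG as
  one unit sampled without replacement (read-level data are no longer
  available after methylation calling); this preserves each site's
  expected methylated fraction.
* `group_contrast()` computes the rank-sum test with mid-ranks and, for
  small samples, an exact permutation-null p-value via a dynamic program
  over the doubled ranks — exact agreement with exhaustive enumeration
  including ties, which the classical normal approximation (used above
  `exact_max` observations) only approximates.
* All stochastic functions take explicit seeds and restore the caller's
  RNG state; identical seeds give bit-identical output.

# Desk-scale validation sizes

The test suite and the acceptance script (`scripts/acceptance.R`)
validate the pipeline at sizes chosen to make every property measurable
in minutes on one CPU: 1,000 random matrices for exact agreement with a
brute-force pair-enumeration oracle; 200 simulated regions per
heterogeneity level for the monotonicity and missing-data properties
(35 cells × 30 CpGs); 800 regions spanning mean methylation 0.07–0.5 for
the normalisation decorrelation (rolling-median window 101); 2,000 genes
× 200 cells for DM behaviour; 2 × 100 cells and 1,000 cohorts for the
correlation direction; 180 clock samples (140 train / 40 held out,
3 seeds); and 20 seeds × 400 promoters for the coupled/decoupled
integration recovery. Genome-scale defaults (rolling window 1000,
Z-window 100) remain the package defaults.

# Known limitations

* **Entropy bias under sparse shared coverage.** The pairwise joint
  entropy is a plug-in estimator; its negative small-sample bias is
  approximately `-(m-1)/(2k·ln 2)` with `m = 4` patterns and `k` shared
  sites. Consequently `H` is systematically attenuated when pairs share
  few CpGs: at 50% missingness on 30-CpG regions (shared coverage
  ~7.5 CpGs per pair) the score drops by roughly 0.1 at intermediate
  heterogeneity, while its *ranking* of regions is far more stable. The
  minimum-shared-sites pair filter and the region coverage filters exist
  precisely to keep comparisons inside a regime where this bias is
  comparable across the groups being contrasted; contrasts between ages
  at matched coverage are unaffected to first order, but absolute `H`
  values from different coverage regimes should not be compared.
* Heterogeneity is scored per region independently; no spatial smoothing
  or neighbour borrowing.
* The similarity-to-young split of old cells into "more" and "less"
  similar groups has no canonical cut; group sizes are caller-supplied.
* The clock assumes the training and target methylomes are on the same
  scale after binning; no cross-platform calibration is attempted.
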