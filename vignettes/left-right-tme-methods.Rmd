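---
title: "Methods: left- versus right-sided tumor microenvironment analysis at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: left- versus right-sided tumor microenvironment analysis at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(tmeside)
```

## Scope and intent

`tmeside` implements, as small tested functions, the computational steps of a
two-condition, multi-sample single-cell RNA-Seq study of the tumor
microenvironment (TME): left-sided versus right-sided colorectal cancer, three
donors per side, 10x-style droplet data. The package covers read-level quality
control, a simplified expression core (normalization, feature selection,
clustering, differential expression), gene-program scoring with trajectory
trends, composition and ratio statistics, centroid similarity structure,
over-representation testing, and permutation-based ligand-receptor scoring.
Every step runs on data from the package's own synthetic generator, so the
whole pipeline is exercised and validated without any download. Datasets of
this design are deposited publicly (e.g. GEO accession GSE188711); the
generator emulates that structure, it does not reproduce any real dataset.

## The synthetic-data generator

`generate_counts()` draws from a hierarchical negative-binomial model chosen
as the simplest generative family that reproduces the two properties the
analysis depends on: overdispersed counts and donor-level variation.

For gene $g$, cell $c$ of type $t(c)$ in sample $s(c)$:

$$
\log \mu_{gc}^{raw} = \beta_g + a_{t(c)} + \delta_{s(c),g}
  + \log(\rho)\,[g \in M_{t(c)}] ,
\qquad
\mu_{gc} = L_c \frac{\mu^{raw}_{gc}}{\sum_{g'} \mu^{raw}_{g'c}},
$$

$$
X_{gc} \sim \mathrm{NB}(\mu_{gc},\ \phi), \qquad
\mathrm{Var}(X_{gc}) = \mu_{gc} + \phi\,\mu_{gc}^2 .
$$

* $\beta_g \sim N(0, \sigma_\beta^2)$ is a per-gene baseline
  (`gene_logmean_sd`, default 1) giving non-marker genes heterogeneous
  expression, so feature selection has realistic structure to work on.
* $a_t$ is the cell type's baseline shift; $M_t$ its marker set and
  $\rho$ the `marker_boost` (default 8), the fold by which markers of the
  cell's own type are raised.
* $\delta_{s,g} \sim N(0, \sigma_s^2)$ is a per-(sample, gene) random effect
  (`sample_effect_sd`, default 0.1) emulating donor variation. It is drawn
  per gene because a scalar per-sample shift would cancel exactly under
  library-size normalization.
* $L_c$ is log-normal with mean `library_size_mean` (default 2500) and CV
  `library_size_cv` (default 0.3); a nonzero CV makes depth normalization a
  real operation rather than a no-op.
* $\phi$ is the overdispersion (`dispersion`, default 0.5); $\phi = 0$
  selects the Poisson limit used by the mean-recovery tests.

Cell types are drawn per cell from the composition column of the sample's
side; the realized type-by-sample table is returned as ground truth. All
draws happen in a fixed order under the config seed, so identical configs
give byte-identical output.

The defaults are the package's study conditions: six samples (3 left, 3
right), 20 clusters, 3,000 cells and 2,000 genes in
`reference_composition_config()`. The real study reports 27,927 cells; 3,000
is the desk-scale stand-in at which all composition, recovery and calibration
claims are tested. `reference_composition_config()` encodes the reported
side-of-origin percentages of the featured clusters (exhausted CD8 67.9%
right, preexhausted CD8 86.8% left, mast 71.5% right, naive CD4 90% right).
Because a cluster's expected side-of-origin fraction depends only on its own
two per-side composition entries (given equal per-side totals), these
fractions are matched exactly in expectation regardless of how the filler
clusters are weighted. Per-sample cell counts are not reported in studies of
this design, so samples get equal counts by default.

What the generator does **not** emulate: ambient RNA, doublets, UMI
collisions, batch-specific dropout curves, and realistic gene-gene
correlation beyond the cell-type programs. Tests passing on this generator
therefore validate the *statistics* (rates, recoveries, calibrations), not
robustness to those artifacts.

## Read-level quality control

`run_read_qc()` applies, per mate and in this order:

1. **Sliding-window trim** — scan 5'→3' with a 4-base window (step 1); cut at
   the start of the first window whose mean Phred quality is below 10.
   Windows that would overhang the 3' end are not evaluated. Cutting at the
   failing window's *start* is the strictest reading of "cut when the mean
   drops below" and makes the retained prefix contain no failing window.
2. **Trailing-base removal** — drop the maximal 3' suffix in which every base
   has quality strictly below 3 or is an `N`.
3. **Adapter removal** — truncate at the leftmost exact full-adapter match,
   else at the longest exact adapter *prefix* (at least `min_overlap = 3`
   bases) flush with the 3' end. Matching is exact; mismatch-tolerant adapter
   alignment is out of scope, and no default adapter is assumed.
4. **Length floor** — a mate retaining fewer than 26 bases is dropped.
5. **Pair rule** — a pair is discarded if either mate was dropped.

Qualities are fixed to Phred+33. `generate_read_fixture()` plants reads of
four known classes (clean, trimmable tail, early adapter, hopeless), so pair
survival is known *by construction*; the test suite also re-derives survival
with an independent per-read hand trace.

## Expression core

* **Normalization** is log1p of counts-per-10,000 (`normalize_log_cp10k()`),
  the de-facto convention of the standard single-cell toolchains. All-zero
  cells are excluded with a warning. Plain fold changes
  (`panel_fold_change()`) are computed on the *linear* CP10K scale
  (`normalize_cp10k()`), since a ratio of means is only meaningful there.
* **Feature selection** (`select_hvg()`) ranks genes by variance/mean of
  normalized expression, z-standardized within equal-frequency mean bins
  (default 20). Ordering ties break by raw dispersion, then gene name, making
  the selection fully deterministic.
* **Clustering** (`cluster_cells()`) z-scales the selected genes, takes
  `n_pcs` principal components (default 20), builds a k-nearest-neighbor
  graph (k = 15, Euclidean in PC space) and partitions it by Louvain
  modularity optimization at resolution 0.6 — the resolution the motivating
  design prescribes. Cross-sample integration is deliberately replaced by
  concatenation: the default donor effect is mild, and integration internals
  are out of scope. Per-cell filtering thresholds are not printed in studies
  of this design; `filter_cells()` defaults to 200 detected genes.
* **Differential expression** uses the two-sided Wilcoxon rank-sum test.
  For combined group sizes of at most 10 the null is enumerated exactly over
  all subset assignments (midranks handle ties); larger groups use the
  normal approximation with tie correction and no continuity correction.
  This split keeps the implementation testable against exhaustive
  enumeration where enumeration is feasible, and fast where it is not.
  Markers (`find_cluster_markers()`) retain genes with |logFC| > 0.5 and
  BH-adjusted p < 0.05, with logFC the difference of group means of
  log-normalized expression (natural log). The pathway-input filter
  (`filter_degs_for_enrichment()`) applies the stricter BH p < 0.01 and
  |log2FC| > 1 (strict inequality: a gene at exactly 1.0 is dropped).
  Benjamini-Hochberg is the only multiple-testing procedure used anywhere.
* **Side contrasts** (`side_degs_per_cluster()`) run the same test and rule
  left-versus-right within each cluster; clusters represented on only one
  side are flagged `NA`, never counted.

## Gene-program scores and trends

Scores are unweighted means of gene-wise Z-scores (`zscore_genes()`,
sample n−1 standard deviation, zero-variance rows mapped to 0 with a
warning) over the signature genes found; missing genes are reported, never
imputed. Whether the Z-transform is taken over all cells or within a
compartment is not fixed by the study design, so the scoring population is
simply whatever matrix the caller passes — score CD8 clusters on the CD8
submatrix to match per-compartment figures.

Shipped signatures: naiveness (CCR7, TCF7, LEF1, SELL), cytotoxicity
(12 genes), and the 24-gene coinhibitory program, exactly as printed in the
motivating design. The 90-gene exhaustion panel is cited there but not
printed, so the package ships a clearly labeled illustrative default
(`inst/extdata/exhaustion_default.txt`) and every test is independent of its
composition; the same holds for the M1/M2 macrophage panels. All signatures
are replaceable via arguments or a plain-text config (`read_signatures()`).

`fit_score_trend()` fits a first-degree LOESS (tricube weights, default span
0.5, exact "direct" surface) of scores on a per-cell trajectory component and
evaluates it on a 100-point grid. Trajectory inference itself is out of
scope: components are accepted as plain numeric input from any source, and
`trajectory_surrogate()` provides the first two PCs of the compartment as an
explicitly labeled plumbing surrogate so the trend step runs end-to-end.

## Composition and similarity structure

`composition_by_side()` produces exact integer counts and two fraction views:
side-of-origin per cluster, and cluster mixture per side. Ratio statistics
(`fold_ratio()`, `exhaustion_ratio_of_ratios()`) consume raw counts — with
one documented exception: the ratio-of-ratios is algebraically invariant to
each cluster's total, so printed side-of-origin percentages can stand in for
counts. That identity,

$$
\frac{n^{pre}_L / n^{exh}_L}{n^{pre}_R / n^{exh}_R}
= \frac{f^{pre}_L \cdot f^{exh}_R}{f^{pre}_R \cdot f^{exh}_L},
$$

is what `scripts/acceptance.R` uses to recompute the reported preexhausted:
exhausted contrast (13.9 from the rounded percentages 86.8%/67.9%).
`fold_ratio(a, 0)` is `NA` by design — undefined is a value, not a crash;
the four-count ratio-of-ratios instead refuses zero counts by name.

Centroids are per-type means of normalized expression over a stated gene
space; the figure-legend convention does not state the space, so it is an
argument defaulting to all supplied genes, with the clustering HVG set as
the recommended choice. `centroid_correlation_network()` uses Pearson
correlation over genes; `hclust_centroids()` clusters centroids with
correlation distance (1 − r) and average (UPGMA) linkage, ordering columns
lexicographically first so ties and tree layout are reproducible, and
refusing constant centroids by name (their correlation is undefined).

`ora_hypergeometric()` is the over-representation stand-in for external
pathway tooling: upper-tail hypergeometric p for each set, BH across the
collection. Pathway databases themselves are out of scope.

## Ligand-receptor permutation test

The cited interaction tool publishes its conventions but not a formula-level
contract, so the package states its own, each a config knob:

* cluster means of normalized expression, masked to 0 for genes detected in
  fewer than 10% of a cluster's cells (`min_expr_frac`);
* multi-subunit complexes (e.g. an a1b1 integrin receptor,
  `ITGA1;ITGB1`) score as the *minimum* subunit mean;
* the pair statistic is the average of the ligand-entity mean in the sender
  and the receptor-entity mean in the receiver, 0 if either entity is
  masked;
* the null shuffles cluster labels over cells `n_perm` times (default
  1000), and `p = (1 + \#\{null \ge obs\}) / (1 + n_perm)` — the add-one
  estimator never returns 0 and yields p = 1 for degenerate nulls; pairs
  observed at 0 are reported with p = 1 and flagged;
* retention follows the strict rule: p ≤ 0.05 is kept, p > 0.05 filtered.

Whether the analysis is pooled or per side is left open by the motivating
design; `permutation_test_lr_by_side()` runs each side separately to mirror
the left/right contrast figures. The packaged ~30-pair list
(`builtin_lr_pairs()`) includes the named axes (TNF→TNFRSF1A,
TNFSF10→TNFRSF10B, TGFB1→TGFBR1, collagen→a1b1) and replaces the external
curated database, which is out of scope.

## Numerical choices and degenerate inputs

* Exact Wilcoxon enumeration engages at n+m ≤ 10; two-sided p is the null
  probability of a rank sum at least as far from its expectation as
  observed (tolerance 1e-9 on the comparison).
* All orderings that could be platform-dependent are pinned: HVG ties by
  dispersion then name, cluster labels by size, dendrogram leaves
  lexicographically, permutations by the supplied seed.
* Zero-variance genes: Z-score 0 with a warning (they contribute a constant
  to any signature score, preserving all rank relations).
* Empty cells are excluded at normalization; empty cell types are dropped
  with a warning in centroid computations; clusters missing a side yield
  `NA` side-DEG counts; `fold_ratio` with a zero denominator is `NA`.
* Clustering with no variable gene returns a single cluster (all cells are
  indistinguishable) rather than erroring.

## Problem sizes used by the test suite

The suite validates statistical claims at sizes chosen to make the claims
sharp yet quick to compute: composition recovery at 10,000 cells against
exact binomial 99% intervals; marker recovery and the planted 2.43× panel
fold (within 10%) at 500–1,000 cells; clustering recovery (adjusted Rand
index 1.0) at 240 cells with well-separated programs; permutation
calibration at 200 cells, ~30 pairs, 1,000 permutations (type-I fraction
≤ 0.07, Kolmogorov-Smirnov uniformity at α = 0.01); read-QC equivalence on
planted fixtures of 100–200 pairs. Null fixtures for the side-DEG and
calibration claims set `sample_effect_sd = 0`, because with a single donor
per side a nonzero donor effect *is* a true side difference — the null claim
requires exchangeable sides.

## Known limitations

* No batch/CCA integration, no trajectory inference, no t-SNE/UMAP quality
  claims — the surrogate components are an ordering device only.
* The exhaustion and M1/M2 defaults are illustrative placeholders, not the
  study-specific panels.
* The generator's independence across genes understates real co-expression;
  calibration results transfer to real data only to the extent that the
  test statistics are rank-based and per-gene.
* Wilcoxon DEG counts depend on sample sizes; at desk scale they are not
  comparable to counts from a 27,927-cell dataset, which is why study-level
  expression figures are validated as recoveries and calibrations, not as
  number-for-number reproductions.
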