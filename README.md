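# tmeside

Left-sided and right-sided colorectal cancers (CRC) are clinically distinct:
they differ in prognosis, molecular pathways, and response to therapy. A
recurring single-cell RNA-Seq design compares the tumor microenvironment
(TME) of the two sides across a handful of donors — typically three
left-sided and three right-sided tumors profiled with 10x droplet
sequencing — and asks which immune programs (T-cell exhaustion, naiveness,
cytotoxicity, macrophage polarization), which cell-type compositions, and
which ligand-receptor circuits distinguish the sides.

`tmeside` implements the computational spine of that design as small,
tested, reusable R functions, and ships a synthetic-data generator that
emulates the study structure so the entire pipeline runs — and is
validated — without downloading anything.

## What is implemented

| Stage | Functions | Statistic / rule |
|---|---|---|
| Read QC | `run_read_qc()`, `sliding_window_trim()`, `trim_trailing()`, `remove_adapter()` | 4-base window, mean Q < 10 cut; trailing Q < 3 or N; exact adapter match/overlap; mates < 26 bp sink the pair |
| Synthetic data | `generate_counts()`, `reference_composition_config()`, `generate_read_fixture()`, `write_tenx_like()` | negative-binomial counts, per-(donor, gene) random effect, planted marker programs, QC truth by construction |
| Expression core | `normalize_log_cp10k()`, `select_hvg()`, `cluster_cells()` | log CP10K; binned-dispersion HVGs; PCA + kNN graph + Louvain at resolution 0.6 |
| Differential expression | `find_cluster_markers()`, `side_degs_per_cluster()`, `filter_degs_for_enrichment()` | Wilcoxon rank-sum (exact for n+m ≤ 10), \|logFC\| > 0.5 & BH p < 0.05; enrichment input at \|log2FC\| > 1 & BH p < 0.01 |
| Signatures | `builtin_signatures()`, `zscore_genes()`, `score_signature()`, `panel_fold_change()`, `fit_score_trend()` | mean of gene-wise Z-scores; naiveness/cytotoxicity/coinhibition panels; linear-scale panel folds; degree-1 LOESS trends |
| Composition | `composition_by_side()`, `fold_ratio()`, `exhaustion_ratio_of_ratios()`, `hclust_centroids()`, `centroid_correlation_network()`, `ora_hypergeometric()` | side-of-origin fractions; ratio-of-ratios identity; 1 − Pearson UPGMA dendrogram; hypergeometric ORA with BH |
| Interactions | `permutation_test_lr()`, `builtin_lr_pairs()`, `filter_significant_pairs()` | cluster-mean statistic, min-subunit complexes, 10% expression mask, add-one permutation p, keep p ≤ 0.05 |

The key composition statistic is the **ratio-of-ratios**: with
$f^{pre}_L$ the left side-of-origin fraction of the preexhausted CD8⁺
cluster and $f^{exh}_R$ the right fraction of the exhausted cluster,

$$
\frac{n^{pre}_L/n^{exh}_L}{n^{pre}_R/n^{exh}_R}
  \;=\; \frac{f^{pre}_L\, f^{exh}_R}{f^{pre}_R\, f^{exh}_L},
$$

because each cluster's total cancels — printed percentages are as good as
raw counts for this contrast.

## Worked example

Simulate the six-sample design at desk scale (3,000 cells, 2,000 genes,
20 cell-type programs whose expected side-of-origin fractions match the
reported featured-cluster percentages), then run composition, clustering
and scoring:

```r
library(tmeside)

cfg <- reference_composition_config(n_cells_per_sample = 500,
                                    n_genes = 2000, seed = 1)
sce <- generate_counts(cfg)

comp <- composition_by_side(data.frame(cluster = sce$cell_type,
                                       side = sce$side,
                                       sample_id = sce$sample_id))
round(comp$side_of_origin[c("CD8_C4_exhausted", "CD8_C6_preexhausted",
                            "Mast"), ], 3)
#>                      side
#> cluster                left right
#>   CD8_C4_exhausted    0.328 0.672
#>   CD8_C6_preexhausted 0.871 0.129
#>   Mast                0.286 0.714

cs <- comp$counts_side
exhaustion_ratio_of_ratios(
  pre_left  = cs["CD8_C6_preexhausted", "left"],
  pre_right = cs["CD8_C6_preexhausted", "right"],
  exh_left  = cs["CD8_C4_exhausted", "left"],
  exh_right = cs["CD8_C4_exhausted", "right"])
#> [1] 13.8  (rounded)

norm <- normalize_log_cp10k(SummarizedExperiment::assay(sce, "counts"))
hv   <- select_hvg(norm, 500)
cl   <- cluster_cells(norm, hv, n_pcs = 20, resolution = 0.6, seed = 1)
nlevels(cl)
#> [1] 20

z <- zscore_genes(norm)
naive <- score_signature(z, builtin_signatures()$naiveness)
mean(naive[sce$cell_type == "CD4_C4_naive"])   # 1.59
mean(naive[sce$cell_type != "CD4_C4_naive"])   # -0.09
```

Reading the output: the exhausted CD8 cluster is right-dominated (67.2%
right here, drawn at a configured 67.9%), the preexhausted cluster
left-dominated (87.1% vs configured 86.8%), and mast cells right-dominated
(71.4% vs configured 71.5%). The left:right ratio of within-side
preexhausted:exhausted ratios comes out at 13.8-fold in this draw. Graph
clustering at the prescribed resolution recovers all 20 planted programs,
and the naive CD4 cluster scores ~1.6 Z-units above the rest on the
4-gene naiveness signature.

## Further reading

The methods vignette (`vignettes/left-right-tme-methods.Rmd`) documents the
generative model and its parameters, every statistical rule and its
thresholds, the numerical conventions (tie-breaks, degenerate inputs,
exact-test cutoffs), the problem sizes at which the test suite validates
each claim, and the package's known limitations.
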