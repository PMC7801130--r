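---
title: "Methods: characterizing CAR T-cell products from single-cell transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing CAR T-cell products from single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartatlas)
```

## The analysis problem

Chimeric antigen receptor (CAR) T-cell products are heterogeneous mixtures:
only a fraction of the cells carry the CAR transgene, only a fraction of
those respond transcriptionally when the CAR meets its antigen, and a small
minority of responders drift toward an exhaustion-like state that matters
clinically. `cartatlas` implements the computational pipeline for
characterizing such products from droplet scRNA-seq UMI counts:

1. quality control and gene filtering;
2. calling CAR-expressing cells from a vector-derived pseudo-feature;
3. normalization, highly-variable-gene (HVG) selection and covariate
   regression;
4. graph-based clustering with a modularity-resolution scan, and
   batch-balanced k-nearest-neighbour label transfer onto leukapheresis
   (starting material) cells;
5. per-gene Welch differential expression with a joint FDR / fold-change /
   base-mean filter;
6. gene-signature scoring with expression-binned control genes, exhaustion
   classification at a fixed score threshold, and the exhausted-vs-least-
   exhausted extreme-cell contrast;
7. hypergeometric over-representation statistics and pre-ranked GSEA with
   the classic (unweighted) running-sum statistic.

Because the pipeline's correctness claims must be checkable without access
to any particular dataset, the package ships a first-class synthetic data
generator (`sim_config()`, `simulate_product()`,
`simulate_leukapheresis()`) that plants known cellular structure and labels;
every stage is tested against that planted truth or against an independent
oracle.

## CAR detection model

Experimentally, CAR transcripts are detected by aligning reads to a
reference extended with the region just upstream of the polyadenylation
site in the vector's 3' long terminal repeat; transcripts ending there mark
transduced cells regardless of integration site. `cartatlas` models the
*result* of that strategy: the count matrix carries an ordinary feature row
(id `"CAR-3LTR"`) holding CAR UMIs per cell, and `detect_car_cells()` flags
a cell as CAR-expressing iff it has at least `min_car_umis` (default 1) CAR
UMIs. Read-level alignment is out of scope.

The CAR row is a vector-derived artifact, not a cellular transcript, so a
standing exclusion list removes it from per-cell totals during
normalization, from HVG selection, and from differential expression. It is
used only by `detect_car_cells()` and CAR-expression-level comparisons
(e.g. exhausted vs non-exhausted responders).

## Quality control

`apply_qc()` keeps cells satisfying all three criteria, with boundary
semantics following the criteria's wording literally:

| criterion | rule | default (product / leukapheresis) |
|---|---|---|
| genes detected | "at least" → `>=` | 1000 / 400 |
| mitochondrial UMI fraction | "less than" → `<` | 0.08 |
| total UMIs | "more than" → `>` | 30,000 / 10,000 |

after which genes with fewer than 2 total UMIs across the retained cells
are dropped (`min_gene_total_umis = 2`, i.e. "more than 1 UMI").
Mitochondrial genes are recognized by the `"MT-"` symbol prefix by default
and can be supplied explicitly. The thresholds are configurable because the
printed UMI floors sit oddly against typical per-cell UMI medians for this
chemistry; the package applies them as stated and does not claim they
reproduce any particular post-QC cell count on real data. QC is idempotent
and reports per-criterion failure counts plus the union.

## Normalization, HVGs, regression

`normalize_log()` scales each cell so its cellular total (CAR excluded)
equals `target_sum = 10000`, then applies `ln(1 + x)`. Zero-total cells
cannot be scaled and are dropped with a warning.

`select_hvgs()` implements the Seurat-flavor mean/dispersion rule: per-gene
mean and dispersion (variance/mean) are computed on the `expm1` scale, the
dispersion is log-transformed and z-scored within 20 equal-frequency bins
of `log1p(mean)`, and a gene is flagged when `0.02 < log1p(mean) < 3` and
the normalized dispersion is at least 0.5. With a `batch_key`, selection
runs within each batch and the flags are merged. The merge rule is a package
decision (the recipe this follows says only "selected within each batch
separately and merged"): a gene is highly variable if flagged in **at least
one** batch, and the list is ordered by (number of batches flagged, median
normalized dispersion). Bins with a single usable gene get normalized
dispersion 0 (there is no spread to standardize against).

`regress_out()` removes per-cell covariates (total UMIs, detected genes,
mitochondrial counts, cell-cycle scores; see `qc_covariates()`) by per-gene
ordinary least squares with an intercept, returning residuals. Constant
covariates are absorbed into the intercept; genuinely collinear covariates
raise an error naming the offending columns.

## Clustering and integration

`pca_embed()` computes centered, unscaled PCA (50 components by default)
with a reproducible sign convention (largest-|loading| gene positive).
`knn_graph()` connects cells listed among each other's `k = 15` Euclidean
nearest neighbours (the within-dataset `k` is not pinned down by the
recipe; 15 is the package default, configurable), weighting edges by the
shared-neighbour count. `cluster_communities()` maximizes modularity at a
given resolution via Leiden (product) or Louvain (leukapheresis), seeded
and deterministic. `resolution_scan()` tabulates cluster count and
modularity over resolutions 0.1–2 (step 0.1) and suggests the **largest**
resolution within 1% of the maximum modularity — an automatable proxy for
the modularity-vs-granularity trade-off; the final resolution remains a
configuration choice, as it is a judgment call in practice.

For integration, the product (reference) and leukapheresis (query) matrices
are subset to their shared HVGs, concatenated, and jointly projected by
PCA, making the shared space explicit. `batch_balanced_neighbors()` finds
each query cell's `k_within = 7` nearest reference cells in that space, and
`transfer_labels()` assigns the mode of the 7 reference labels. Mode ties
are broken by the label of the nearest tied-label neighbour — a
deterministic, distance-respecting rule chosen by this package (the
upstream description is silent on ties).

`umap_embed()` (via `uwot`, single-threaded for determinism) exists for
visualization only; nothing downstream consumes its coordinates.

## Differential expression

`welch_ttest_by_gene()` computes, per gene, the unequal-variance t
statistic with Welch–Satterthwaite degrees of freedom and two-sided
p-values, BH-adjusted across genes (`bh_adjust()`, delegating to
`stats::p.adjust`). Zero-variance genes yield `p = 1` when the group means
agree and `p = 0` flagged `degenerate` otherwise — never `NaN`.

The fold-change and base-mean conventions are package decisions, since the
source analyses do not print their formulas:

* `log2_fold_change = log2((mean_A' + 1e-9) / (mean_B' + 1e-9))`, where
  `mean'` is the group mean of `expm1`(ln-normalized expression), clamped
  at zero for residual-type inputs;
* `log2_mean_expr = log2(pooled mean of expm1 expression + 1e-9)`, which
  makes base-mean thresholds of −5 / −7 / −3 interpretable on a log2 scale.

`apply_de_filter()` applies the three joint criteria with strict
inequalities: `q < 0.05`, `|log2FC| > 1`, `log2 mean > −5` (or −7 / −3 per
analysis). `top_upregulated()` returns the top 200 positive-fold-change
genes ranked by ascending q then descending fold change ("most
upregulated" is otherwise unspecified). `overlap_cluster()` binarizes
per-comparison upregulated lists over their union and applies Ward
clustering (`hclust`, `ward.D2`) on Euclidean distances to genes and
comparisons, cutting the gene tree into 5 groups by default.

## Signature scoring and exhaustion classification

`score_signature()` re-implements the binned-control scheme: genes are
ranked by average expression and split into `n_bins = 25` equal-frequency
bins; for each signature gene, `ctrl_per_gene = 50` control genes are
sampled (seeded) from its bin, excluding signature genes; the score is the
mean expression of the signature genes minus the mean of the pooled
controls. Controls are addressed by sorted gene id, so scores are invariant
to the gene order of the matrix, and adding a constant to the matrix leaves
scores unchanged. When a bin holds fewer candidates than `ctrl_per_gene`,
sampling falls back to replacement with a warning. The two parameters are
defaults of the widely used implementation of this scheme; the source
recipe names the function but not its internals.

Scores are computed on ln-normalized (not regressed) expression by default:
regression residuals are mean-shifted in ways that distort the bin means.
Both paths are available.

`intersect_signature()` restricts a symbol-based signature to the HVGs (the
documented instance being a 107-gene exhaustion signature reducing to 26
HVG members). `classify_exhausted()` calls a cell exhausted iff its score
is **strictly** greater than 0.6. `select_extremes()` picks the top-`n` and
bottom-`n` cells by score within a mask (default `n = 153`), breaking ties
by barcode order.

The packaged signature (`exhaustion_signature()`,
`inst/extdata/exhaustion_signature_synthetic.gmt`) is a **synthetic
stand-in**: the original supplementary gene list is not redistributable
from the text alone, so the package ships the exhaustion genes named in the
results narrative (LAG3, HAVCR2, CTLA4, TIGIT, TBX21, IFNG, CCL1, CCL3,
CCL4, CCL5, ENTPD1) plus canonical chronic-stimulation markers (PDCD1, TOX,
EOMES, ...). Any GMT can be substituted.

## Enrichment statistics

`hypergeom_upper_pval(x, N, m, k)` is the upper-tail probability
`P(X >= x)` of drawing `x` of `m` marked genes when sampling `k` from `N`,
computed with `stats::phyper` (log-gamma based) and verified against
exhaustive enumeration. The printed summation bound in the source formula
("min(n, B)") uses symbols it never defines; the package uses `min(k, m)`,
the only bound under which the distribution is proper. `enrich_terms()`
applies it per term for the up and down lists, BH-corrects across terms,
and reports the up/down overlap ratio `log2(x_up / x_down)` for significant
terms. Edge cases the formula's source does not address: a zero denominator
gives an `Inf` sentinel (cap it at plotting time); zero over zero is `NA`.

`rank_genes_for_gsea()` scores genes by `(1 / q) * sign(log2FC)` with q
clipped below at 1e-300; `sign(0) = 0` puts fold-change-free genes
mid-list. `gsea_preranked()` implements the classic (unweighted) statistic:
the running sum gains `1/n_hits` at set members and loses
`1/(n_total − n_hits)` elsewhere; ES is the signed maximum deviation. The
null is gene-tag permutation (random same-size sets, seeded, default 1000);
the nominal p is the smoothed fraction of same-sign null ES at least as
extreme; NES divides ES by the mean |null ES| of the same sign; FDR q
follows the standard GSEA tail-ratio procedure over the set collection.
Sets with fewer than 15 or more than 500 members in the ranking are skipped
with a reason. The weighted (p = 1) statistic is deliberately not offered.

## The synthetic generator

`simulate_product()` draws, per donor and condition:

1. **cluster structure** — four base programs (CD4 central-memory, CD4
   effector-memory, CD8 central-memory, CD8 effector; proportions
   0.30/0.25/0.25/0.20) defined by fold-shifts on identity and memory
   markers (CD4, CD8A/B, CCR7, SELL, GZMA/B, NKG7) plus 30 dedicated
   program genes each, and an **activated** program (up: IL2RA, MYC, GZMB,
   IL2, IL3, IL4, IL5, IL8, IL13, CSF2, CCR4, BATF3, IRF4 and 30 synthetic
   activation genes; down: SELL, CD3D/E/G, B2M);
2. **planted labels** — 22.5% CAR-positive cells per sample; in the
   stimulated arm 50% of CAR+ cells become responders (activated program)
   of which 7% are additionally exhausted (LAG3, HAVCR2, CTLA4, TIGIT,
   TBX21, IFNG, CCL1, CCL3, CCL4, CCL5, ENTPD1 up); in the unstimulated arm
   7% of CAR+ cells are pre-activated. Planted counts use floor +
   largest-remainder allocation, so configured fractions reproduce exactly;
3. **noise** — per-donor per-gene log-normal effects (sd 0.03), per-cell
   log-normal library sizes (mean ≈ 60,000 UMIs, so default cells clear the
   30,000-UMI QC floor), negative-binomial counts (dispersion 0.1), a
   Beta-distributed mitochondrial share (mean 5%, so a realistic minority of
   cells fail the 8% cutoff), and S/G2M cell-cycle programs on 8%/7% of
   cells;
4. **the CAR pseudo-feature** — CAR+ cells draw NB CAR UMIs with mean 5,
   doubled for exhausted cells (their elevated CAR expression); CAR−
   cells get exactly zero.

`simulate_leukapheresis()` drops the CAR and activation programs and adds a
2% CD3E-negative, GNLY/NKG7-high contaminant population.

**Effect sizes are free parameters.** The study conditions fix the
*fractions* (22.5%, 50%, 7%, 7%) and the sample layout (3 donors ×
conditions; 6,234 cells per condition per donor ≈ 37,400 product cells);
they say nothing quantitative about program strength. The defaults —
program fold 4, activation fold 6, exhaustion fold 12, donor effect sd
0.03, low baselines for inducible genes — were chosen once so that the
planted populations are separable by the pipeline's own machinery, which is
precisely what makes recovery tests meaningful. The donor effect is kept
small in aggregate because, across hundreds of HVGs, a per-gene log-sd of
0.1 would dominate program structure and split every cluster by donor,
contradicting the observed donor-mixed cluster composition the generator
emulates. These are documented package choices, not measured values.

**What the generator does not emulate:** ambient RNA, doublets (doublet
removal is out of pipeline scope), batch chemistry effects beyond a
multiplicative donor term, realistic gene-gene correlation beyond the
planted programs, zero-inflation beyond what the NB yields, or the true
sparsity profile of 20,000-gene references (the default universe is 2,000
genes with correspondingly denser per-gene counts). Passing recovery tests
on this generator therefore demonstrates internal correctness of the
pipeline's logic and statistics, not performance on any real dataset.

## Numerical and reproducibility choices

* All stochastic stages take explicit seeds; `run_pipeline()` derives
  per-stage seeds from one master seed and writes an md5 manifest of every
  artifact, so two runs with the same config are hash-identical.
* Report percentages use half-up rounding at the precision conventionally
  printed (integer for the exhausted share, one decimal elsewhere), always
  recomputed from stored counts.
* Welch statistics guard zero-variance genes; BH is the exact step-up;
  `phyper` gives log-gamma stability for genome-scale `N`.
* Tie-breaks are deterministic everywhere: barcode order for score ties,
  nearest-neighbour label for transfer ties, input order for allocation
  remainder ties.

## Problem sizes used by the test-suite

Unit and property tests run the generator at 60–2,000 cells per
condition-donor and 600–2,000 genes — large enough for the binomial and
recovery tolerances they assert (e.g. 12,000 cells for the CAR-fraction
check, ~3,000 responders for the ±2-percentage-point exhaustion recovery)
and small enough for a routine single-CPU run. `scripts/acceptance.R` runs
the stimulated arm at the full default scale (18,702 cells). These sizes
are the package's own validation design.

## Known limitations

* The exhaustion signature shipped is a synthetic reconstruction (see
  above); results on real data should use the intended published list.
* The activated-cluster identification in `run_pipeline()` (the cluster
  where stimulated CAR+ cells concentrate) assumes stimulation produces
  such a cluster; on data without a stimulated arm the activation contrast
  is skipped.
* The modularity-based resolution suggestion is a proxy; biological
  granularity judgments cannot be automated away.
* GSEA FDR follows the standard pooled-null procedure; with a single gene
  set it degenerates toward the nominal p.
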