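---
title: "Stratifying colorectal tumors by two stem-like programs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying colorectal tumors by two stem-like programs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcss)
```

## The scientific problem

Colorectal cancer carries at least two transcriptionally distinct
stem-like tumor-cell populations: the canonical LGR5⁺ compartment, driven
by WNT signaling, and a second population marked by *LAPTM4B* with MYC
pathway activity, an expression-level gain of chromosome arm 8q (the arm
harboring both *LAPTM4B* and *MYC*), and near-exclusive presence in
microsatellite-stable tumors. The relative activity of the two programs
in a bulk tumor sample defines four stem-like subtypes (CSS1–CSS4) with
different recurrence risk: LAPTM4B-dominant tumors (CSS2) fare worst,
LGR5-dominant tumors (CSS4) best. `crcss` implements the statistics of
that stratification end to end, with synthetic cohorts standing in for
patient data.

## Models and procedures

### Normalization

All single-cell differential expression and scoring operates on
counts-per-10k, log1p-transformed values (`normalize_log1p()`), the
field-standard library-size transform. Bulk matrices are treated as
log-scale and, before signature scoring, standardized gene-wise to zero
mean and unit variance within each cohort (`scale_within_cohort()`), so
that scores from different cohorts share a scale and the cohort-median
thresholds are comparable. Because the CSS rule is rank-based, any
monotone rescaling of one score axis leaves the assignment unchanged.

### Ro/e tissue enrichment

For a cluster-by-group count table, `roe()` returns
`obs(i, j) / expected(i, j)` with
`expected(i, j) = row_i · col_j / total`. Values above 1 indicate
enrichment beyond what the margins predict. Entries whose expected count
is zero are returned as `NA`, not a number.

### Differential expression

`diff_expr()` uses the two-sided Wilcoxon rank-sum test per gene — the
standard non-parametric cluster-marker test in single-cell practice — in
a vectorized normal approximation with tie correction and continuity
correction (appropriate at the group sizes here, hundreds of cells). The
fold change is computed on the de-logged normalized scale with a `1e-9`
pseudocount, reported as log2 by default (the base is configurable). FDR
is Benjamini–Hochberg across all tested genes. Genes zero in both groups
get `log2_fc = 0`, `p = 1` by convention.

### Rank-based gene-set AUC (stemness scoring)

`gene_set_auc()` scores each cell by how early the signature genes appear
in that cell's expression ranking: with `k = ceil(top_fraction · G)`
(default top 5 %), the score is the area under the step curve of
cumulative signature hits over ranks `1..k`, normalized by the maximal
achievable area. The score lives in [0, 1], depends only on ranks (hence
is invariant to monotone transforms of a cell's profile), and is
monotone: promoting a signature gene in the ranking can never lower it.
Rank ties are broken by one fixed seeded shuffle so results are
deterministic.

### Expression-inferred arm scores

`infer_arm_scores()` is a deliberately minimal copy-number scan: per gene
`log2(CP10k + 1)`, centered by the mean over user-chosen reference
(copy-number-neutral) clusters, clamped at ±3 log2 units, smoothed by a
101-gene moving average along genomic order within each chromosome, then
averaged per arm per cell and per cluster. There is no HMM and no
subclustering — the score's only job is to flag an arm-level expression
shift such as the 8q gain, for which a mean shift test is sufficient.
Clamp and window follow common practice for expression-CNV heatmaps;
both are arguments. `gain_call` fires above `+0.1`, a default set well
above the simulated null noise floor (about 0.02 under the null
configuration described below); arms with fewer than 30 located genes
yield `NA` calls. Smoothing is internal and gene-order invariant; arm
assignment comes from the user's locus table (1-based starts), with no
cytoband inference.

### Marker discovery and signatures

`call_cluster_marker()` intersects three sets: genes upregulated in the
candidate cluster versus all other malignant epithelial cells, genes
upregulated versus its sibling stem-like cluster, and genes on the
nominated arm — at strict thresholds logFC > 2, FDR < 0.01. On the
default synthetic dataset this returns exactly the five planted 8q
markers. `build_signature()` applies the analogous two-contrast
intersection (malignant epithelium vs other cells; stem-like cluster vs
other malignant subpopulations) at gentler defaults (logFC > 1,
FDR < 0.05), because signature membership needs genes expressed broadly
enough to survive the compartment-level contrast; genes are ordered by
the within-epithelium fold change. The named core genes of both programs
ship as `default_signatures()` for users without single-cell data.

### CSS assignment and the combined predictor

`score_samples()` takes the median standardized log expression of the
signature genes (missing genes are dropped with a warning; below 50 %
coverage is an error). `assign_css()` thresholds each axis at the cohort
median — the median suits the skewed score distributions — and maps the
quadrants to CSS1 (low/low), CSS2 (LAPTM4B-dominant), CSS3 (high/high),
CSS4 (LGR5-dominant). Ties at the median count as "low": the published
descriptions of median-threshold stratification leave ties unspecified,
and strict inequality keeps the
degenerate all-constant case well defined (everything CSS1) while
guaranteeing exactly ⌊n/2⌋ "high" calls per axis for tie-free scores.
`combined_marker_score()` is `log expr(LAPTM4B) − log expr(LGR5)`, the
monotone equivalent of the LAPTM4B/LGR5 expression ratio; monotone
equivalence preserves ROC and AUC exactly.

### Outcome statistics

Kaplan–Meier, log-rank and Cox regression are delegated to the mature
`survival` package (`survfit`, `survdiff`, `coxph` with the Breslow tie
approximation — adequate at the tie rates of continuous simulated times,
and the simplest documented choice). `cox_fit()` refuses constant
covariates, too few events, and non-converged or separated fits. ROC/AUC
is computed from mid-ranks (Mann–Whitney identity; ties count one half),
which equals the trapezoidal area under the empirical ROC. Mutation
enrichment is a per-gene two-sided Fisher exact test (2×2, group by
mutated status) with BH correction across genes; mutational burden is
compared by Welch t-tests, with a zero-variance/equal-means pair reported
as p = 1 by convention.

## The synthetic cohorts

### What they emulate

`simulate_sc()` draws negative-binomial counts (shared dispersion 0.5,
baseline mean 0.5 counts per gene per cell — sparse, overdispersed,
droplet-like) for six clusters: the LGR5-type stem cluster (20 % of
cells, a 30-gene program at 6-fold), the LAPTM4B-type stem cluster (12 %,
five 8q markers at 4-fold, restricted to MSS patients), two non-stem
tumor clusters, and two normal epithelial clusters (marker programs at
4-fold each). The gain cluster's 8q genes — 10 % of the 2,000-gene panel —
are additionally multiplied by `arm_gain_factor` (default 2), modeling
the 8q gain as a uniform expression shift rather than a DNA-level event:
sufficient for an expression-based detector. The magnitude of the real
8q expression shift is not quantified in the source literature, so the
factor is an explicit free parameter. The synthetic locus table places
the five planted markers on 8q (two of them, *LAPTM4B* and *MYC*, really
reside there; the placement of the remaining three is a simulation
convenience) and spreads other genes over the remaining arms.

`simulate_bulk()` adds the two program effects (unit log-scale effect,
Gaussian noise SD 0.5) to a Gaussian baseline according to the planted
subtype — CSS1 neither, CSS2 LAPTM4B, CSS3 both, CSS4 LGR5 — in equal
proportions by default. Survival is exponential with hazard
`0.006 · exp(log HR)` per month over a 60-month horizon with 20 % extra
uniform censoring; the default log-HRs are `log 2.31` for CSS2 (the
headline high-risk subtype), `log 1.5` for the intermediate CSS1/CSS3,
and 0 for CSS4. Under the dedicated two-subtype recovery condition
(n = 600) this yields roughly 40 % events, and the Cox estimate is exact
in expectation because the exponential model satisfies proportional
hazards exactly. Mutations are Bernoulli with subtype-specific
frequencies (TP53 0.75 in CSS2; APC 0.84/0.78 in CSS3/CSS4; BRAF
concentrated in CSS1), and mutational burden is negative binomial with a
four-fold elevated mean in the MSI-enriched CSS1.

All randomness flows from one master seed through named substreams, so
regenerating one component (e.g. survival times) never perturbs another,
and identical configs give bit-identical output.

### What they do not emulate

No doublets, ambient RNA, batch effects, patient-level expression
variation, read-level noise, cell-type proportions drifting with clinical
covariates, DNA-level copy-number segments, or correlated mutation
co-occurrence. Passing tests therefore demonstrate that the statistics
recover the structure they assume, at realistic sparsity and noise — not
that the pipeline is robust to the artifacts of real data, which is what
the preprocessing tools excluded from this package's scope are for.

## Numerical choices and degenerate inputs

* Wilcoxon p-values use the tie-corrected normal approximation with
  continuity correction; a zero-variance gene gets p = 1.
* The arm-score null floor scales as
  `1 / sqrt(genes-per-arm × cells)`; the packaged null check uses 500
  query cells against a 1,500-cell reference over a 4,000-gene panel, a
  gene density comparable to real expression-CNV panels, where the floor
  is ~0.02 against the 0.1 gain threshold.
* An empty marker intersection is a valid empty result; an empty
  signature intersection is an error (a signature must be non-empty) with
  advice to relax thresholds.
* The strict-inequality tie rule makes all-constant score vectors
  classifiable (all CSS1) instead of undefined.
* Fisher, BH and AUC implementations are cross-checked in the test suite
  against exhaustive enumeration oracles (all 2×2 tables with margins
  ≤ 12; step-up definition; positive–negative pair counting).

## Problem sizes used in the packaged checks

The packaged checks run the single-cell recovery conditions at 2,000
genes × 3,000 cells over 20 seeds, CSS recovery at 400 bulk samples,
Cox recovery at n = 600 over 50 seeds, log-rank calibration over 1,000
null replicates of n = 120, and the combined-predictor comparison on
AUCs pooled over 10 cohorts of n = 1,000 — the pooling is needed because
the population AUC margin of the combined score over each single marker
under subtype-level hazards is ~0.02, below single-cohort sampling noise.

## Known limitations

* The Wilcoxon normal approximation is unreliable below ~10 cells per
  group; the package refuses groups under 3 and is intended for the
  hundreds-of-cells regime.
* The arm score is relative to the chosen reference clusters; a
  contaminated reference shifts all scores. The reference set is a
  required user input.
* Cox fitting assumes proportional hazards, which the exponential
  simulator satisfies by construction; real cohorts need the usual
  diagnostics.
* The derived LAPTM4B-type signature can be short (2–4 genes) when the
  compartment-level contrast is underpowered for a small cluster; the
  median score over few genes is noisier, which mainly affects the CSS2
  axis.
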