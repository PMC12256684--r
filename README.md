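# crcss — stem-like subtype stratification of colorectal cancer

Colorectal tumors harbor more than one stem-like cell population. Besides
the canonical LGR5⁺ (WNT-driven) compartment, a second, MYC-associated
stem-like population marked by *LAPTM4B* — a gene on chromosome arm 8q —
carries an arm-wide 8q expression gain, concentrates in
microsatellite-stable (MSS) tumors, and is linked to recurrence. `crcss`
implements the full desk-side pipeline behind that stratification for
analysts working with single-cell and bulk colorectal transcriptomes:

1. **Cell-population statistics** — observed/expected tissue enrichment
   (Ro/e = `obs(i,j) / (row_i · col_j / total)`), two-group Wilcoxon
   differential expression with Benjamini–Hochberg FDR, and a rank-based
   per-cell gene-set AUC (the area under the recovery curve of signature
   genes within the top 5 % of each cell's expression ranking).
2. **Expression-inferred arm scores** — a simplified copy-number scan
   (reference-centered `log2` expression, clamped at ±3, 101-gene moving
   average, averaged per arm and cluster) that flags the 8q gain.
3. **Marker and signature discovery** — three-way intersection
   `{up vs rest} ∩ {up vs sibling stem cluster} ∩ {8q genes}` at
   logFC > 2, FDR < 0.01 for the arm-linked marker, and a two-contrast
   intersection for the stem-like signatures.
4. **CSS classification** — per-sample signature scores are the median
   log expression of the signature genes; each sample is called high/low
   per axis at the cohort median, giving four subtypes: CSS1 (low/low),
   CSS2 (LAPTM4B-dominant), CSS3 (high/high), CSS4 (LGR5-dominant).
5. **Outcome statistics** — Kaplan–Meier, log-rank, Cox proportional
   hazards (Breslow ties), ROC/AUC by the Mann–Whitney rank identity, the
   combined `LAPTM4B − LGR5` log-expression recurrence score, per-gene
   Fisher mutation enrichment, and Welch comparisons of mutational burden.

Because real patient cohorts cannot ship with a package, `crcss` includes
seeded synthetic generators (`simulate_sc()`, `simulate_bulk()`) that
plant the exact structure the analysis assumes — two stem-like clusters,
an 8q gain, four bulk subtype profiles, subtype-dependent exponential
survival and mutation frequencies — so every stage is testable against a
known ground truth.

## Worked example

```r
library(crcss)
res <- run_pipeline(pipeline_config(seed = 1))

res$marker_call$markers
#> [1] "C4orf48" "EREG"    "LAPTM4B" "MYC"     "TNNC2"

subset(res$arm_scores, cluster == "stem_laptm4b" & arm == "8q")
#>         cluster arm     score n_genes gain_call
#>    stem_laptm4b  8q     0.740     200      TRUE

mean(as.character(res$css$subtype) == res$truth$bulk_subtype)
#> [1] 0.8975

res$cox[res$cox$term == "subtypeCSS2", c("term", "hr", "p_value")]
#>          term       hr  p_value
#>   subtypeCSS2     1.51    0.069
```

The pipeline recovers all five planted 8q markers with no false
positives, scores the planted 8q gain at 0.74 (every other arm below
0.31), and reassigns ~90 % of bulk samples to their planted subtype. At
n = 400 the CSS2-vs-CSS4 hazard ratio is estimated with wide error bars
(1.51 above); the dedicated recovery condition in the acceptance script
(two subtypes, n = 600, ~40 % events) recovers the planted 2.31 within
its sampling band, as do 92 % of 50 replicate seeds in the test suite.

The same steps can be driven from files: the numbered scripts in
`analysis/` simulate the cohorts (`01`), compute Ro/e and stemness scores
(`02`), detect the 8q gain and call the marker (`03`), derive signatures
and assign CSS (`04`), and run the outcome statistics (`05`), writing
their tables under `results/`.

## Vignette

`vignettes/css-stratification.Rmd` describes the statistical model behind
every stage, the tunable thresholds and their defaults, what the
synthetic cohorts do and do not emulate, and the package's known
limitations.
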