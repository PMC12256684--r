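#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study cohorts.
#
# Simulates (i) a single-cell epithelial dataset with two planted stem-like
# clusters (LGR5-type; LAPTM4B-type with an arm-wide 8q expression gain,
# restricted to MSS patients) and (ii) a 400-sample bulk cohort mixing the
# two programs into four subtype profiles with subtype-dependent survival
# and mutations. Raw data land in scratch/sim/ (workspace); small summary
# tables in results/.

library(crcss)

seed <- 1L
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

sc <- simulate_sc(default_sc_config(seed = seed))
write_expression(sc$counts, "scratch/sim/sc_counts.mtx", "mtx")
write_tsv_table(sc$cells, "scratch/sim/sc_cells.tsv")
write_tsv_table(sc$loci, "scratch/sim/gene_loci.tsv")
write_tsv_table(
  data.frame(cell = names(sc$truth$cluster), cluster = sc$truth$cluster),
  "scratch/sim/sc_truth.tsv"
)

bulk <- simulate_bulk(default_bulk_config(n_samples = 400, seed = seed))
write_expression(bulk$expr, "scratch/sim/bulk_expr.tsv", "tsv")
write_tsv_table(bulk$clinical, "scratch/sim/bulk_clinical.tsv")
write_tsv_table(
  cbind(data.frame(sample = rownames(bulk$mutations)),
        as.data.frame(bulk$mutations)),
  "scratch/sim/bulk_mutations.tsv"
)
write_tsv_table(
  data.frame(sample = names(bulk$subtype), subtype = bulk$subtype),
  "scratch/sim/bulk_truth.tsv"
)

summary_tab <- data.frame(
  dataset = c("single_cell", "bulk"),
  units = c(ncol(sc$counts), ncol(bulk$expr)),
  genes = c(nrow(sc$counts), nrow(bulk$expr)),
  seed = seed
)
write_tsv_table(summary_tab, "results/01_cohort_sizes.tsv")
message("single-cell: ", ncol(sc$counts), " cells x ", nrow(sc$counts),
        " genes; bulk: ", ncol(bulk$expr), " samples. Seed ", seed, ".")
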