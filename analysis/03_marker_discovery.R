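#!/usr/bin/env Rscript
# Stage 3 — 8q gain detection and marker discovery.
#
# Scores every chromosome arm per cluster with the expression-inferred
# copy-number score (normal clusters as reference) and intersects the two
# upregulation contrasts with the 8q gene list to call the LAPTM4B-type
# cluster's markers.

library(crcss)

counts <- read_expression("scratch/sim/sc_counts.mtx", "mtx")
cells <- as.data.frame(data.table::fread("scratch/sim/sc_cells.tsv"))
loci <- read_gene_loci("scratch/sim/gene_loci.tsv")

normal_clusters <- unique(cells$cluster[cells$tissue == "normal"])
arm <- infer_arm_scores(counts, cells, loci,
                        reference_clusters = normal_clusters)
write_tsv_table(arm, "results/03_arm_scores.tsv")
g <- arm[arm$cluster == "stem_laptm4b", ]
message("stem_laptm4b 8q arm score: ", round(g$score[g$arm == "8q"], 3),
        " (next-highest arm ",
        round(max(g$score[g$arm != "8q"]), 3), "); gain called: ",
        g$gain_call[g$arm == "8q"])

de_rest <- as.data.frame(data.table::fread("scratch/sim/de_laptm4b_vs_epi.tsv"))
de_sib <- as.data.frame(data.table::fread("scratch/sim/de_laptm4b_vs_lgr5.tsv"))
mk <- call_cluster_marker(de_rest, de_sib, loci, arm = "8q")
write_tsv_table(data.frame(marker = mk$markers), "results/03_markers_8q.tsv")
message("8q markers at logFC > 2, FDR < 0.01 in both contrasts: ",
        paste(mk$markers, collapse = ", "))
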