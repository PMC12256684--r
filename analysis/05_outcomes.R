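#!/usr/bin/env Rscript
# Stage 5 — outcomes: survival by subtype, the combined two-marker
# predictor, and the mutation landscape.

library(crcss)

bulk <- read_expression("scratch/sim/bulk_expr.tsv", "tsv", values = "log")
clinical <- read_clinical("scratch/sim/bulk_clinical.tsv")
mutations <- read_mutations("scratch/sim/bulk_mutations.tsv")
css <- as.data.frame(data.table::fread("results/04_css_calls.tsv"))
grp <- css$subtype[match(clinical$sample, css$sample)]

km <- km_estimate(clinical$time, clinical$event, grp)
write_tsv_table(km, "results/05_km_by_css.tsv")
lr <- logrank_test(clinical$time, clinical$event, grp)
cox <- cox_fit(clinical$time, clinical$event,
               data.frame(subtype = relevel(factor(grp), ref = "CSS4")))
write_tsv_table(cox, "results/05_cox_css_vs_css4.tsv")
message("Log-rank across CSS subtypes: chi-square ",
        round(lr$statistic, 2), " (df ", lr$df, "), p = ",
        signif(lr$p_value, 3), ". CSS2 vs CSS4 HR = ",
        round(cox$hr[cox$term == "subtypeCSS2"], 2), ".")

cmb <- combined_marker_score(bulk)
aucs <- data.frame(
  predictor = c("combined_laptm4b_minus_lgr5", "laptm4b", "lgr5_negated"),
  auc = c(roc_auc(cmb, clinical$event)$auc,
          roc_auc(bulk["LAPTM4B", ], clinical$event)$auc,
          roc_auc(-bulk["LGR5", ], clinical$event)$auc)
)
write_tsv_table(aucs, "results/05_roc_auc.tsv")
message("Recurrence AUC - combined: ", round(aucs$auc[1], 3),
        ", LAPTM4B alone: ", round(aucs$auc[2], 3),
        ", LGR5 alone (protective, negated): ", round(aucs$auc[3], 3), ".")

me <- mutation_enrichment(mutations, grp, pair = c("CSS2", "CSS4"))
write_tsv_table(me, "results/05_mutation_enrichment_css2_vs_css4.tsv")
tmb <- tmb_compare(clinical$tmb, grp)
write_tsv_table(tmb, "results/05_tmb_pairwise.tsv")
top <- me[which.min(me$q_value), ]
message("Most enriched mutation in CSS2 vs CSS4: ", top$gene, " (",
        round(100 * top$freq_a), "% vs ", round(100 * top$freq_b),
        "%, q = ", signif(top$q_value, 3), ").")
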