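# End-to-end orchestration: single-cell stage (enrichment, arm scores,
# marker call, signature derivation) feeding the bulk stage (scoring, CSS
# assignment, survival, ROC, mutations), with a provenance record that
# suffices to re-run bit-identically.

#' Pipeline configuration
#'
#' @param seed Master seed for both simulators.
#' @param sc,bulk Simulator configs ([sc_sim_config()] /
#'   [bulk_sim_config()]); defaults are the study conditions of
#'   [default_sc_config()] / [default_bulk_config()] reseeded from `seed`.
#' @param lfc_min_marker,fdr_max_marker Thresholds of the 8q marker call.
#' @param lfc_min_signature,fdr_max_signature Thresholds of signature
#'   derivation.
#' @param top_fraction Gene-set AUC top fraction.
#' @param gain_threshold Arm-score gain threshold.
#' @param min_coverage Signature coverage floor for bulk scoring.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, sc = NULL, bulk = NULL,
                            lfc_min_marker = 2, fdr_max_marker = 0.01,
                            lfc_min_signature = 1, fdr_max_signature = 0.05,
                            top_fraction = 0.05, gain_threshold = 0.1,
                            min_coverage = 0.5) {
  if (is.null(sc)) sc <- default_sc_config(seed = seed)
  if (is.null(bulk)) bulk <- default_bulk_config(seed = seed)
  structure(
    list(seed = as.integer(seed), sc = sc, bulk = bulk,
         lfc_min_marker = lfc_min_marker, fdr_max_marker = fdr_max_marker,
         lfc_min_signature = lfc_min_signature,
         fdr_max_signature = fdr_max_signature,
         top_fraction = top_fraction, gain_threshold = gain_threshold,
         min_coverage = min_coverage),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full stratification pipeline on simulated cohorts
#'
#' Simulates a single-cell cohort, derives the two stem-like signatures and
#' the 8q marker call from it, simulates a bulk cohort carrying the planted
#' programs, scores and stratifies the bulk samples into CSS1-CSS4, and
#' computes the outcome statistics. Deterministic given the config.
#'
#' @param config A [pipeline_config()] (or a path to a YAML file with the
#'   scalar fields of one).
#' @return List with elements `roe`, `arm_scores`, `marker_call`,
#'   `signatures`, `stemness_scores`, `css`, `km`, `logrank`, `cox`, `roc`,
#'   `mutation_enrichment`, `tmb`, `truth`, and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    y <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, y)
  }
  stopifnot(inherits(config, "pipeline_config"))

  sc <- stage("simulate_sc", simulate_sc(config$sc))
  norm <- stage("normalize", normalize_log1p(sc$counts))

  roe_tab <- stage("roe", roe(table(sc$cells$cluster, sc$cells$tissue)))

  tumor <- sc$cells$cell[sc$cells$tissue == "tumor"]
  normal <- sc$cells$cell[sc$cells$tissue == "normal"]
  clus <- function(x) sc$cells$cell[sc$cells$cluster == x]
  tumor_not <- function(x) setdiff(tumor, clus(x))

  de <- stage("diff_expr", list(
    epi_vs_other = diff_expr(norm, tumor, normal),
    lgr5_vs_epi = diff_expr(norm, clus("stem_lgr5"),
                            tumor_not("stem_lgr5")),
    laptm4b_vs_epi = diff_expr(norm, clus("stem_laptm4b"),
                               tumor_not("stem_laptm4b")),
    laptm4b_vs_lgr5 = diff_expr(norm, clus("stem_laptm4b"),
                                clus("stem_lgr5"))
  ))

  normal_clusters <- unique(sc$cells$cluster[sc$cells$tissue == "normal"])
  arm_scores <- stage("arm_scores",
    infer_arm_scores(sc$counts, sc$cells, sc$loci,
                     reference_clusters = normal_clusters,
                     gain_threshold = config$gain_threshold))

  marker <- stage("marker_call",
    call_cluster_marker(de$laptm4b_vs_epi, de$laptm4b_vs_lgr5, sc$loci,
                        arm = "8q", lfc_min = config$lfc_min_marker,
                        fdr_max = config$fdr_max_marker))

  sigs <- stage("signatures", list(
    lgr5 = build_signature(de$epi_vs_other, de$lgr5_vs_epi,
                           lfc_min = config$lfc_min_signature,
                           fdr_max = config$fdr_max_signature,
                           name = "LGR5_stem"),
    laptm4b = build_signature(de$epi_vs_other, de$laptm4b_vs_epi,
                              lfc_min = config$lfc_min_signature,
                              fdr_max = config$fdr_max_signature,
                              name = "LAPTM4B_stem")
  ))

  stemness <- stage("stemness_auc", {
    a <- gene_set_auc(norm, sigs$lgr5, top_fraction = config$top_fraction)
    b <- gene_set_auc(norm, sigs$laptm4b, top_fraction = config$top_fraction)
    data.frame(cell = a$cell, cluster = sc$cells$cluster,
               auc_lgr5 = a$score, auc_laptm4b = b$score,
               stringsAsFactors = FALSE)
  })

  bulk <- stage("simulate_bulk", simulate_bulk(config$bulk))
  scaled <- stage("scale_bulk", scale_within_cohort(bulk$expr))

  css <- stage("assign_css", {
    s_l <- score_samples(scaled, sigs$lgr5, min_coverage = config$min_coverage)
    s_b <- score_samples(scaled, sigs$laptm4b,
                         min_coverage = config$min_coverage)
    assign_css(s_l, s_b)
  })

  cl <- bulk$clinical
  grp <- as.character(css$subtype)
  km <- stage("km", km_estimate(cl$time, cl$event, grp))
  lr <- stage("logrank", logrank_test(cl$time, cl$event, grp))
  cox <- stage("cox", {
    cox_fit(cl$time, cl$event,
            data.frame(subtype = stats::relevel(factor(grp), ref = "CSS4")))
  })

  roc <- stage("roc", {
    cmb <- combined_marker_score(bulk$expr)
    list(combined = roc_auc(cmb, cl$event),
         laptm4b = roc_auc(bulk$expr["LAPTM4B", ], cl$event),
         lgr5 = roc_auc(-bulk$expr["LGR5", ], cl$event))
  })

  mut <- stage("mutation_enrichment",
               mutation_enrichment(bulk$mutations, grp,
                                   pair = c("CSS2", "CSS4")))
  tmb <- stage("tmb", tmb_compare(cl$tmb, grp))

  provenance <- list(
    package_version = as.character(utils::packageVersion("crcss")),
    seed = config$seed,
    thresholds = config[c("lfc_min_marker", "fdr_max_marker",
                          "lfc_min_signature", "fdr_max_signature",
                          "top_fraction", "gain_threshold", "min_coverage")],
    sc_config = sc$truth$config,
    bulk_config = bulk$config
  )

  list(roe = roe_tab, arm_scores = arm_scores, marker_call = marker,
       signatures = sigs, stemness_scores = stemness, css = css,
       km = km, logrank = lr, cox = cox, roc = roc,
       mutation_enrichment = mut, tmb = tmb,
       truth = list(sc = sc$truth, bulk_subtype = bulk$subtype),
       provenance = provenance)
}
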