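# Shared simulation fixtures, generated in code. The small configurations
# trade power for speed and are used where only mechanics are under test;
# the full-size default configs are reserved for recovery checks.

small_sc_config <- function(seed = 1L, n_cells = 600) {
  default_sc_config(seed = seed, n_cells = n_cells, n_genes = 500)
}

# Reference/query pair from one distribution: the null condition for the
# arm-score noise floor (dense gene panel, 500 query cells).
null_arm_config <- function(seed = 1L) {
  sc_sim_config(
    n_genes = 4000, n_cells = 2000,
    clusters = list(
      cluster_spec("reference", 0.75, tissue = "normal"),
      cluster_spec("query", 0.25, tissue = "tumor")
    ),
    seed = seed
  )
}

# Two planted subtypes (CSS2 vs CSS4) with a chosen hazard ratio and ~40%
# events; used for Cox/log-rank recovery and calibration.
two_group_surv_config <- function(seed, n = 600, log_hr = log(2.3)) {
  bulk_sim_config(
    n_samples = n, subtype_proportions = c(0, 0.5, 0, 0.5),
    lgr5_program = c(LGR5 = 1), laptm4b_program = c(LAPTM4B = 1),
    survival = surv_sim_spec(
      baseline_hazard = 0.006,
      log_hr_per_subtype = c(CSS1 = 0, CSS2 = log_hr, CSS3 = 0, CSS4 = 0),
      censor_rate = 0.2, horizon_months = 60
    ),
    n_genes = 5, seed = seed
  )
}

planted_8q_markers <- function() {
  sort(c("LAPTM4B", "MYC", "TNNC2", "EREG", "C4orf48"))
}

# Derive the two stem-like DE contrasts of a simulated single-cell dataset.
sc_contrasts <- function(sc) {
  norm <- normalize_log1p(sc$counts)
  cl <- function(x) sc$cells$cell[sc$cells$cluster == x]
  tumor <- sc$cells$cell[sc$cells$tissue == "tumor"]
  list(
    norm = norm,
    epi_vs_other = diff_expr(norm, tumor,
                             sc$cells$cell[sc$cells$tissue == "normal"]),
    lgr5_vs_epi = diff_expr(norm, cl("stem_lgr5"),
                            setdiff(tumor, cl("stem_lgr5"))),
    laptm4b_vs_epi = diff_expr(norm, cl("stem_laptm4b"),
                               setdiff(tumor, cl("stem_laptm4b"))),
    laptm4b_vs_lgr5 = diff_expr(norm, cl("stem_laptm4b"), cl("stem_lgr5"))
  )
}
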