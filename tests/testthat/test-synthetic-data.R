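# Generator contracts: determinism, planted means, composition, and the
# validation of malformed configurations.

test_that("single-cell simulation is deterministic given seed and config", {
  a <- simulate_sc(small_sc_config(seed = 5))
  b <- simulate_sc(small_sc_config(seed = 5))
  expect_identical(a$counts, b$counts)
  expect_identical(a$cells, b$cells)
  expect_identical(a$loci, b$loci)
  d <- simulate_sc(small_sc_config(seed = 6))
  expect_false(identical(a$counts, d$counts))
})

test_that("null configuration gives equal cluster-wise gene means", {
  sc <- simulate_sc(null_sc_config(seed = 3, n_cells = 1500))
  cl <- sc$cells$cluster
  grand <- rowMeans(sc$counts)
  for (g in sample(rownames(sc$counts), 25)) {
    for (cc in unique(cl)) {
      x <- sc$counts[g, cl == cc]
      se <- stats::sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - grand[g]), max(3 * se, 0.2))
    }
  }
})

test_that("planted marker fold is recovered in empirical means", {
  sc <- simulate_sc(default_sc_config(seed = 2, n_cells = 3000))
  cl <- sc$cells$cluster
  # epi_prolif markers carry a plain 4-fold (no arm gain on top)
  for (g in sc$truth$markers$epi_prolif[1:5]) {
    inside <- sc$counts[g, cl == "epi_prolif"]
    outside <- sc$counts[g, cl != "epi_prolif"]
    se <- sqrt(stats::var(inside) / length(inside) +
                 16 * stats::var(outside) / length(outside))
    expect_lt(abs(mean(inside) - 4 * mean(outside)), 3 * se)
  }
  # the gain cluster's 8q markers carry marker_fold * arm_gain_factor
  g <- "LAPTM4B"
  inside <- sc$counts[g, cl == "stem_laptm4b"]
  expect_gt(mean(inside), 6 * mean(sc$counts[g, cl == "ent_normal"]))
})

test_that("cluster composition is multinomial at configured fractions", {
  sc <- simulate_sc(default_sc_config(seed = 4, n_cells = 3000))
  fr <- vapply(sc$truth$config$clusters, `[[`, numeric(1), "fraction")
  obs <- table(factor(sc$cells$cluster, levels = names(fr))) / 3000
  for (k in names(fr)) {
    expect_lt(abs(obs[[k]] - fr[[k]]),
              4 * sqrt(fr[[k]] * (1 - fr[[k]]) / 3000))
  }
})

test_that("MSS restriction confines the gain cluster to MSS patients", {
  sc <- simulate_sc(small_sc_config(seed = 1))
  expect_true(all(sc$cells$msi[sc$cells$cluster == "stem_laptm4b"] == "MSS"))
  expect_true(any(sc$cells$msi == "MSI"))
})

test_that("gain-cluster markers are placed on 8q, other markers off 8q", {
  sc <- simulate_sc(small_sc_config(seed = 1))
  on_8q <- sc$loci$gene[sc$loci$chrom == "8" & sc$loci$arm == "q"]
  expect_true(all(sc$truth$markers$stem_laptm4b %in% on_8q))
  expect_false(any(sc$truth$markers$stem_lgr5 %in% on_8q))
  expect_false(anyDuplicated(sc$loci$start[sc$loci$chrom == "8" &
                                             sc$loci$arm == "q"]) > 0)
})

test_that("invalid single-cell configs are rejected", {
  cls <- list(cluster_spec("a", 0.5, tissue = "tumor"),
              cluster_spec("b", 0.4, tissue = "normal"))
  expect_error(sc_sim_config(500, 100, cls), "sum to 1")
  cls2 <- list(cluster_spec("a", 0.5, marker_genes = "nope", marker_fold = 2),
               cluster_spec("b", 0.5, tissue = "normal"))
  expect_error(sc_sim_config(500, 100, cls2, frac_8q_genes = 0.05),
               "at least 50")
  overlapping <- list(
    cluster_spec("a", 0.5, marker_genes = c("M1", "M2"), marker_fold = 2),
    cluster_spec("b", 0.5, marker_genes = c("M2", "M3"), marker_fold = 2,
                 tissue = "normal")
  )
  expect_error(sc_sim_config(500, 100, overlapping), "disjoint")
})

test_that("bulk simulation is deterministic and validates proportions", {
  a <- simulate_bulk(default_bulk_config(n_samples = 50, seed = 9))
  b <- simulate_bulk(default_bulk_config(n_samples = 50, seed = 9))
  expect_identical(a$expr, b$expr)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$mutations, b$mutations)
  expect_error(
    bulk_sim_config(50, subtype_proportions = c(0.3, 0.3, 0.3, 0.2),
                    lgr5_program = c(LGR5 = 1),
                    laptm4b_program = c(LAPTM4B = 1)),
    "sum to 1"
  )
})

test_that("planted mutation frequency lands in its binomial 99% band", {
  cfg <- default_bulk_config(n_samples = 400, seed = 11)
  b <- simulate_bulk(cfg)
  in_css2 <- b$subtype == "CSS2"
  n2 <- sum(in_css2)
  obs <- mean(b$mutations[in_css2, "TP53"])
  half_width <- stats::qnorm(0.995) * sqrt(0.75 * 0.25 / n2)
  expect_lt(abs(obs - 0.75), half_width)
})

test_that("null survival simulation gives calibrated log-rank p-values", {
  ps <- vapply(1:200, function(s) {
    b <- simulate_bulk(two_group_surv_config(seed = s, n = 120, log_hr = 0))
    logrank_test(b$clinical$time, b$clinical$event, b$subtype)$p_value
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
})

test_that("planted hazard ratio is recovered by the Cox fit", {
  b <- simulate_bulk(two_group_surv_config(seed = 1, n = 600))
  fit <- cox_fit(b$clinical$time, b$clinical$event,
                 data.frame(css2 = as.integer(b$subtype == "CSS2")))
  expect_gt(fit$hr, 1.8)
  expect_lt(fit$hr, 2.9)
  expect_gt(mean(b$clinical$event), 0.3)
  expect_lt(mean(b$clinical$event), 0.5)
})
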