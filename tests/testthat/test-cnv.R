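# Expression-inferred arm scores and the three-way 8q marker intersection.

test_that("window = 1 reproduces unsmoothed reference-centered values", {
  set.seed(1)
  n_g <- 60
  counts <- matrix(rpois(n_g * 40, 5), n_g, 40,
                   dimnames = list(sprintf("g%02d", 1:n_g),
                                   sprintf("c%02d", 1:40)))
  ann <- data.frame(cell = colnames(counts),
                    cluster = rep(c("ref", "qry"), each = 20))
  loci <- data.frame(gene = rownames(counts),
                     chrom = rep(c("1", "2"), each = n_g / 2),
                     arm = rep(c("p", "q"), times = n_g / 2),
                     start = rep(seq_len(n_g / 2) * 1000, 2))
  res <- infer_arm_scores(counts, ann, loci, "ref", window = 1,
                          min_genes = 1)
  # hand computation of one (cluster, arm) score
  totals <- colSums(counts)
  v <- log2(sweep(counts, 2, totals / 1e4, "/") + 1)
  v <- v - rowMeans(v[, 1:20])
  v[v > 3] <- 3
  v[v < -3] <- -3
  arm_genes <- loci$gene[loci$chrom == "1" & loci$arm == "q"]
  hand <- mean(colMeans(v[arm_genes, 21:40]))
  expect_equal(res$score[res$cluster == "qry" & res$arm == "1q"], hand)
})

test_that("arm scores are invariant to gene-row permutation of the input", {
  sc <- simulate_sc(small_sc_config(seed = 2))
  ref <- c("ent_normal", "gob_normal")
  a1 <- infer_arm_scores(sc$counts, sc$cells, sc$loci, ref)
  perm <- sample(nrow(sc$counts))
  a2 <- infer_arm_scores(sc$counts[perm, ], sc$cells,
                         sc$loci[rev(seq_len(nrow(sc$loci))), ], ref)
  key <- function(a) a[order(a$cluster, a$arm), ]
  expect_equal(key(a1)$score, key(a2)$score)
})

test_that("a planted 2-fold 8q gain produces the maximal arm score", {
  sc <- simulate_sc(default_sc_config(seed = 3))
  a <- infer_arm_scores(sc$counts, sc$cells, sc$loci,
                        c("ent_normal", "gob_normal"))
  g <- a[a$cluster == "stem_laptm4b", ]
  s8q <- g$score[g$arm == "8q"]
  expect_gt(s8q, 0.1)
  expect_equal(s8q, max(g$score))
  expect_true(g$gain_call[g$arm == "8q"])
})

test_that("query cells from the reference distribution score near zero", {
  sc <- simulate_sc(null_arm_config(seed = 1))
  a <- infer_arm_scores(sc$counts, sc$cells, sc$loci, "reference")
  expect_lt(max(abs(a$score[a$cluster == "query"])), 0.05)
  expect_false(any(a$gain_call[a$cluster == "query"], na.rm = TRUE))
})

test_that("the 8q arm score grows monotonically with the planted gain", {
  scores <- vapply(c(1, 1.5, 2, 3), function(f) {
    cfg <- default_sc_config(seed = 11, n_cells = 1000)
    cfg$arm_gain_factor <- f
    sc <- simulate_sc(cfg)
    a <- infer_arm_scores(sc$counts, sc$cells, sc$loci,
                          c("ent_normal", "gob_normal"))
    a$score[a$cluster == "stem_laptm4b" & a$arm == "8q"]
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("infer_arm_scores validates its inputs", {
  sc <- simulate_sc(small_sc_config(seed = 4))
  expect_error(infer_arm_scores(sc$counts, sc$cells, sc$loci,
                                character()), "reference")
  expect_error(infer_arm_scores(sc$counts, sc$cells, sc$loci,
                                "ent_normal", window = 4), "odd")
  expect_error(infer_arm_scores(sc$counts, sc$cells, sc$loci[1:50, ],
                                "ent_normal"), "80%")
})

test_that("marker intersection is exact set algebra", {
  de1 <- data.frame(gene = c("A", "B", "C", "D"),
                    log2_fc = c(3, 3, 0, 3), fdr = c(1e-4, 1e-4, 1e-4, 1e-4))
  de2 <- data.frame(gene = c("A", "B", "C", "D"),
                    log2_fc = c(3, 0, 3, 3), fdr = c(1e-4, 1e-4, 1e-4, 0.5))
  loci <- data.frame(gene = c("A", "Z", "D"), chrom = "8", arm = "q",
                     start = c(1, 2, 3))
  mk <- call_cluster_marker(de1, de2, loci, "8q")
  expect_identical(mk$markers, "A") # B fails contrast 2, C contrast 1, D FDR
  mk2 <- call_cluster_marker(de1, de2, loci, "8q", lfc_min = Inf)
  expect_length(mk2$markers, 0)
})

test_that("marker calls are monotone in the thresholds", {
  sc <- simulate_sc(small_sc_config(seed = 5))
  d <- sc_contrasts(sc)
  tight <- call_cluster_marker(d$laptm4b_vs_epi, d$laptm4b_vs_lgr5,
                               sc$loci, "8q", lfc_min = 2, fdr_max = 0.01)
  loose <- call_cluster_marker(d$laptm4b_vs_epi, d$laptm4b_vs_lgr5,
                               sc$loci, "8q", lfc_min = 1, fdr_max = 0.05)
  expect_true(all(tight$markers %in% loose$markers))
})

test_that("marker call rejects mismatched universes, allows empty results", {
  de1 <- data.frame(gene = c("A", "B"), log2_fc = c(3, 3), fdr = c(1, 1))
  de2 <- data.frame(gene = c("A", "C"), log2_fc = c(3, 3), fdr = c(1, 1))
  loci <- data.frame(gene = "A", chrom = "8", arm = "q", start = 1)
  expect_error(call_cluster_marker(de1, de2, loci), "universe")
  de2$gene <- c("A", "B")
  mk <- call_cluster_marker(de1, de2, loci) # nothing passes fdr < 0.01
  expect_length(mk$markers, 0)
})
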