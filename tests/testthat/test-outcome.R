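# Survival and association statistics against hand calculations and
# brute-force oracles.

test_that("Kaplan-Meier matches the product-limit rule by hand", {
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$surv[km$time == 1], 0.5)
  expect_equal(km$surv[km$time == 2], 0)
  all_cens <- km_estimate(c(3, 5, 7), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("duplicating every record leaves the KM curve unchanged", {
  set.seed(1)
  t <- rexp(30, 0.1)
  e <- rbinom(30, 1, 0.6)
  k1 <- km_estimate(t, e)
  k2 <- km_estimate(rep(t, 2), rep(e, 2))
  expect_equal(k1$surv, k2$surv)
  expect_equal(k1$time, k2$time)
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(2)
  t <- sample(1:20, 15, replace = TRUE)
  km <- km_estimate(t, rep(1, 15))
  for (i in seq_len(nrow(km))) {
    expect_equal(km$surv[i], mean(t > km$time[i]))
  }
})

test_that("log-rank is zero for identical groups, matches the O-E oracle", {
  t <- c(2, 4, 6, 8)
  e <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # disjoint event-time blocks, no censoring, n = 6
  t2 <- 1:6
  e2 <- rep(1, 6)
  grp <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(t2, e2, grp)
  expect_equal(lr$statistic, logrank_oracle(t2, e2, grp == "a"))
  expect_error(logrank_test(t2, rep(0, 6), grp), "no events")
  expect_error(logrank_test(t2, e2, rep("a", 6)), "two")
})

test_that("Cox on identical groups gives HR 1; HR is time-scale invariant", {
  t <- c(2, 4, 6, 8, 10, 12)
  e <- c(1, 1, 0, 1, 1, 0)
  cov1 <- data.frame(g = rep(0:1, each = 6))
  f1 <- cox_fit(rep(t, 2), rep(e, 2), cov1)
  expect_equal(f1$hr, 1, tolerance = 1e-6)
  set.seed(3)
  tt <- rexp(80, 0.1 * exp(0.5 * rep(0:1, 40)))
  ee <- rbinom(80, 1, 0.8)
  cov2 <- data.frame(g = rep(0:1, 40))
  a <- cox_fit(tt, ee, cov2)
  b <- cox_fit(tt * 12, ee, cov2)
  expect_equal(a$hr, b$hr, tolerance = 1e-8)
  expect_error(cox_fit(tt, ee, data.frame(g = rep(1, 80))), "constant")
})

test_that("Cox score direction and p agree with the log-rank test", {
  b <- simulate_bulk(two_group_surv_config(seed = 4, n = 400))
  cl <- b$clinical
  g <- as.integer(b$subtype == "CSS2")
  fit <- cox_fit(cl$time, cl$event, data.frame(g = g))
  lr <- logrank_test(cl$time, cl$event, g)
  expect_gt(fit$hr, 1)
  expect_equal(log(fit$p_value), log(lr$p_value), tolerance = 0.1)
})

test_that("ROC AUC matches hand values and the pair-counting oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3))$auc, 1)
  expect_equal(roc_auc(rep(5, 8), rep(0:1, each = 4))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(5)
  for (i in 1:20) {
    s <- sample(1:6, 30, replace = TRUE) # heavy ties
    l <- rbinom(30, 1, 0.4)
    if (sum(l) == 0 || sum(l) == 30) next
    expect_equal(roc_auc(s, l)$auc, auc_oracle(s, l))
    expect_equal(roc_auc(s, l)$auc + roc_auc(-s, l)$auc, 1)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  s <- rnorm(80)
  l <- rbinom(80, 1, 0.5)
  expect_equal(
    roc_auc(s, l)$auc,
    as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  )
})

test_that("Fisher enrichment p-values match hand and oracle values", {
  mut <- rbind(matrix(c(rep(1, 5), rep(0, 5)), ncol = 1),
               matrix(c(rep(1, 5), rep(0, 5)), ncol = 1))
  colnames(mut) <- "G1"
  rownames(mut) <- paste0("s", 1:20)
  grp <- rep(c("a", "b"), each = 10)
  res <- mutation_enrichment(mut, grp)
  expect_equal(res$p_value, 1) # balanced 5/5 vs 5/5
  mut2 <- matrix(rep(c(1, 0), each = 10), ncol = 1,
                 dimnames = list(paste0("s", 1:20), "G1"))
  res2 <- mutation_enrichment(mut2, grp) # 10/0 vs 0/10
  expect_equal(res2$p_value, 2 / choose(20, 10))
  expect_equal(res2$p_value, fisher_oracle(10, 0, 0, 10))
})

test_that("mutation enrichment validates inputs and applies BH", {
  set.seed(7)
  mut <- matrix(rbinom(200, 1, 0.3), 20, 10,
                dimnames = list(paste0("s", 1:20), paste0("G", 1:10)))
  grp <- rep(c("a", "b"), each = 10)
  res <- mutation_enrichment(mut, grp)
  expect_equal(res$q_value, bh_oracle(res$p_value))
  expect_error(mutation_enrichment(mut, grp, pair = c("a", "zz")),
               "zero samples")
  expect_error(mutation_enrichment(mut * 2, grp), "binary")
})

test_that("TMB comparisons are symmetric, calibrated, and powered", {
  x <- c(1, 2, 3, 4, 5, 6)
  same <- tmb_compare(c(x, x), rep(c("a", "b"), each = 6))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  set.seed(8)
  a <- rnorm(50, 10, 2)
  b <- rnorm(50, 16, 2) # 3 SD shift
  res <- tmb_compare(c(a, b), rep(c("a", "b"), each = 50))
  expect_lt(res$p_value, 1e-6)
  swapped <- tmb_compare(c(b, a), rep(c("a", "b"), each = 50))
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_value, res$p_value)
  expect_message(
    zv <- tmb_compare(rep(5, 8), rep(c("a", "b"), each = 4)),
    "zero-variance"
  )
  expect_equal(zv$p_value, 1)
  expect_error(tmb_compare(1:5, c("a", "a", "a", "b", "b")), "fewer than 3")
})
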