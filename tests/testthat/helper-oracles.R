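# Independent brute-force oracles used to cross-check the package's
# statistics. These are deliberately naive implementations.

# Ro/e by explicit loops over the margin definition.
roe_oracle <- function(m) {
  out <- matrix(NA_real_, nrow(m), ncol(m))
  total <- sum(m)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / total
      out[i, j] <- if (e == 0) NA_real_ else m[i, j] / e
    }
  }
  out
}

# Two-sided Fisher exact p by exhaustive enumeration of the hypergeometric
# support: sum of probabilities of tables no more likely than the observed.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(supp, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up from its definition:
# q_(i) = min(1, min_{j >= i} p_(j) * n / j).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in rev(seq_len(n - 1))) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# AUC by counting every positive-negative pair (ties worth 1/2).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# Gene-set recovery-curve AUC by explicit step-curve enumeration given the
# ranks of the signature genes.
recovery_auc_oracle <- function(sig_ranks, n_genes, n_sig, top_fraction) {
  k <- ceiling(top_fraction * n_genes)
  cum <- vapply(seq_len(k), function(i) sum(sig_ranks <= i), numeric(1))
  m <- min(n_sig, k)
  sum(cum) / sum(pmin(seq_len(k), m))
}

# Two-group log-rank chi-square by manual observed-minus-expected
# tabulation over event times (no censoring handling beyond risk sets).
logrank_oracle <- function(time, event, in_a) {
  ts <- sort(unique(time[event == 1]))
  o_a <- 0
  e_a <- 0
  v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & in_a)
    d <- sum(event == 1 & time == t)
    d_a <- sum(event == 1 & time == t & in_a)
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (o_a - e_a)^2 / v
}
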