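# Cell-population statistics: Ro/e tissue enrichment, Wilcoxon differential
# expression with BH control, and rank-based per-cell gene-set AUC scoring.

#' Observed-to-expected enrichment ratio (Ro/e)
#'
#' For a cluster-by-group contingency table, computes the ratio of the
#' observed count to the count expected from the table margins:
#' `expected(i, j) = row_total(i) * col_total(j) / grand_total`. Values
#' above 1 indicate enrichment of a cluster in a group, values below 1
#' depletion.
#'
#' @param counts Non-negative integer matrix (clusters x groups).
#' @return Matrix of Ro/e values; entries with zero expected count are `NA`.
#' @examples
#' roe(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
#' @export
roe <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0) stop("empty contingency table")
  if (any(counts < 0)) stop("contingency table has negative entries")
  total <- sum(counts)
  if (total <= 0) stop("contingency table grand total must be positive")
  expected <- outer(rowSums(counts), colSums(counts)) / total
  out <- counts / expected
  out[expected == 0] <- NA_real_
  out
}

# Vectorised two-sided Wilcoxon rank-sum p-values (normal approximation with
# tie correction and continuity correction; the standard large-n marker-test
# approximation). Rows of `x` are genes; `ia`/`ib` index the two groups.
wilcox_rows <- function(x, ia, ib) {
  na <- length(ia)
  nb <- length(ib)
  n <- na + nb
  cols <- c(ia, ib)
  mu <- na * nb / 2
  vapply(seq_len(nrow(x)), function(g) {
    v <- x[g, cols]
    r <- data.table::frank(v, ties.method = "average")
    u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    cnt <- tabulate(match(v, v))
    cnt <- cnt[cnt > 0]
    tie_term <- sum(cnt^3 - cnt)
    sigma2 <- (na * nb / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    min(1, 2 * stats::pnorm(-z))
  }, numeric(1))
}

#' Two-group differential expression (Wilcoxon rank-sum + BH)
#'
#' Per gene: a two-sided Wilcoxon rank-sum p-value between the two groups of
#' cells/samples, a log2 fold change computed on the de-logged normalized
#' scale with a small pseudocount, and Benjamini-Hochberg adjusted FDR
#' across all tested genes.
#'
#' @param mat Log-normalized gene-by-unit matrix (see [normalize_log1p()]).
#' @param group_a,group_b Disjoint column indices or names, each of size >= 3.
#' @param eps Pseudocount used in the fold change (default 1e-9).
#' @param lfc_base Logarithm base for the fold change (default 2).
#' @return `data.frame` with columns `gene`, `log2_fc`, `p_value`, `fdr`,
#'   `mean_a`, `mean_b`.
#' @export
diff_expr <- function(mat, group_a, group_b, eps = 1e-9, lfc_base = 2) {
  mat <- as.matrix(mat)
  assert_lognorm(mat, "expression matrix")
  resolve <- function(g) {
    if (is.character(g)) match(g, colnames(mat)) else as.integer(g)
  }
  ia <- resolve(group_a)
  ib <- resolve(group_b)
  if (anyNA(ia) || anyNA(ib)) stop("group members missing from matrix columns")
  if (length(intersect(ia, ib)) > 0) stop("groups overlap")
  if (length(ia) < 3 || length(ib) < 3) stop("each group needs at least 3 units")

  lin <- expm1(mat)
  mean_a <- rowMeans(lin[, ia, drop = FALSE])
  mean_b <- rowMeans(lin[, ib, drop = FALSE])
  lfc <- log((mean_a + eps) / (mean_b + eps), base = lfc_base)
  zero_both <- mean_a == 0 & mean_b == 0
  lfc[zero_both] <- 0

  p <- wilcox_rows(mat, ia, ib)
  p[zero_both] <- 1
  genes <- rownames(mat)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(mat)))
  data.frame(
    gene = genes,
    log2_fc = lfc,
    p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    mean_a = mean_a,
    mean_b = mean_b,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Rank-based per-cell gene-set AUC score
#'
#' AUCell-style enrichment: for every cell, genes are ranked by decreasing
#' expression (ties broken by a fixed seeded shuffle), and the score is the
#' area under the recovery curve of signature genes within the top
#' `top_fraction` of the ranking, normalized by the maximal achievable area.
#' A score of 1 means all signature genes sit at the very top of the
#' ranking; 0 means none fall inside the top fraction. Because only ranks
#' are used, the score is invariant under any strictly increasing transform
#' of a cell's expression vector.
#'
#' @param mat Gene-by-cell expression matrix with rownames.
#' @param gene_set Character vector of signature genes (or a
#'   `gene_signature` object).
#' @param top_fraction Fraction of the ranking that counts as "top"
#'   (default 0.05, the conventional choice).
#' @param tie_seed Seed for the deterministic tie-breaking shuffle.
#' @return `data.frame` with columns `cell` and `score` (in `[0, 1]`);
#'   attribute `top_fraction` records the fraction used.
#' @export
gene_set_auc <- function(mat, gene_set, top_fraction = 0.05, tie_seed = 0L) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("matrix must have gene rownames")
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must be in (0, 1)")
  }
  genes <- signature_genes(gene_set)
  present <- intersect(genes, rownames(mat))
  if (length(present) == 0) {
    stop("no signature genes found in matrix; missing: ",
         paste(utils::head(genes, 10), collapse = ", "))
  }
  g <- nrow(mat)
  k <- ceiling(top_fraction * g)
  m <- min(length(present), k)
  max_area <- sum(pmin(seq_len(k), m))
  sig_idx <- match(present, rownames(mat))
  tie_perm <- with_substream(tie_seed, "auc-tie-shuffle", sample.int(g))

  scores <- vapply(seq_len(ncol(mat)), function(j) {
    ord <- order(-mat[, j], tie_perm)
    rnk <- integer(g)
    rnk[ord] <- seq_len(g)
    rs <- rnk[sig_idx]
    rs <- rs[rs <= k]
    sum(k - rs + 1) / max_area
  }, numeric(1))

  cells <- colnames(mat)
  if (is.null(cells)) cells <- paste0("cell", seq_len(ncol(mat)))
  out <- data.frame(cell = cells, score = scores, stringsAsFactors = FALSE)
  attr(out, "top_fraction") <- top_fraction
  out
}
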