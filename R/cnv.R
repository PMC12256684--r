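# Expression-inferred arm-level copy-number scores (simplified inferCNV:
# reference-centered, clamped, windowed moving average — no HMM) and the
# three-way intersection that calls a cluster-specific arm marker.

# Running mean down the rows of M with an odd window, truncated at the
# edges, computed with a cumulative-sum trick for all columns at once.
running_mean_cols <- function(M, window) {
  n <- nrow(M)
  if (window <= 1 || n == 1) return(M)
  half <- (window - 1L) %/% 2L
  cs <- rbind(0, apply(M, 2L, cumsum))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

#' Expression-inferred arm-level copy-number scores
#'
#' Simplified copy-number inference from expression: per gene,
#' `log2(normalized + 1)` is centered by the mean over reference cells,
#' clamped to `+/- clamp` log2 units, and smoothed by a moving average of
#' width `window` over genes ordered by genomic position (within each
#' chromosome). Per-cell arm values are the mean of the arm's smoothed
#' genes; per-cluster scores are the mean over the cluster's cells. An arm
#' score well above 0 flags an expression-level gain of that arm in that
#' cluster.
#'
#' @param counts Gene-by-cell matrix. Raw counts are normalized internally
#'   (counts per 10k); a log1p-normalized matrix is accepted and de-logged.
#' @param annotation Data frame with columns `cell` and `cluster` aligned
#'   to matrix columns.
#' @param loci Gene locus table with columns `gene`, `chrom`, `arm`,
#'   `start` (1-based); must cover at least 80% of matrix genes.
#' @param reference_clusters Cluster labels treated as copy-number-neutral
#'   reference (e.g. normal epithelial clusters).
#' @param window Odd moving-average width in genes (default 101).
#' @param clamp Symmetric clamp for centered values, log2 units (default 3).
#' @param gain_threshold Score above which `gain_call` is `TRUE`
#'   (default 0.1, set from the null-simulation noise floor).
#' @param min_genes Arms with fewer located genes get `gain_call = NA`
#'   (default 30).
#' @return `data.frame` with columns `cluster`, `arm` (e.g. `"8q"`),
#'   `score`, `n_genes`, `gain_call`.
#' @export
infer_arm_scores <- function(counts, annotation, loci, reference_clusters,
                             window = 101L, clamp = 3, gain_threshold = 0.1,
                             min_genes = 30L) {
  counts <- as.matrix(counts)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (length(reference_clusters) == 0) stop("reference clusters required")
  if (is.null(rownames(counts))) stop("matrix must have gene rownames")
  if (!all(c("cell", "cluster") %in% names(annotation))) {
    stop("annotation needs 'cell' and 'cluster' columns")
  }
  cl <- annotation$cluster[match(colnames(counts), annotation$cell)]
  if (anyNA(cl)) stop("annotation does not cover all matrix columns")
  ref_cells <- which(cl %in% reference_clusters)
  if (length(ref_cells) == 0) stop("no cells in reference clusters")

  located <- intersect(rownames(counts), loci$gene)
  if (length(located) / nrow(counts) < 0.8) {
    stop("loci table covers < 80% of matrix genes")
  }

  norm <- if (is_lognorm(counts)) expm1(counts) else {
    totals <- colSums(counts)
    totals[totals == 0] <- 1
    sweep(counts, 2L, totals / 1e4, "/")
  }
  v <- log2(norm + 1)
  v <- v - rowMeans(v[, ref_cells, drop = FALSE])
  v[v > clamp] <- clamp
  v[v < -clamp] <- -clamp

  li <- loci[match(located, loci$gene), ]
  ord <- order(suppressWarnings(as.integer(li$chrom)), li$chrom,
               li$arm, li$start)
  li <- li[ord, ]
  v <- v[li$gene, , drop = FALSE]

  # smooth within each chromosome so arms of different chromosomes never mix
  for (ch in unique(li$chrom)) {
    idx <- which(li$chrom == ch)
    v[idx, ] <- running_mean_cols(v[idx, , drop = FALSE], window)
  }

  arm_id <- paste0(li$chrom, li$arm)
  arms <- unique(arm_id)
  dropped <- setdiff(unique(paste0(loci$chrom, loci$arm)), arms)
  if (length(dropped)) {
    warning("arms without located genes omitted: ",
            paste(dropped, collapse = ", "))
  }
  clusters <- unique(cl)
  res <- expand.grid(cluster = clusters, arm = arms,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$score <- NA_real_
  res$n_genes <- NA_integer_
  for (a in arms) {
    gi <- which(arm_id == a)
    arm_cell <- colMeans(v[gi, , drop = FALSE])
    for (cc in clusters) {
      i <- which(res$cluster == cc & res$arm == a)
      res$score[i] <- mean(arm_cell[cl == cc])
      res$n_genes[i] <- length(gi)
    }
  }
  res$gain_call <- ifelse(res$n_genes < min_genes, NA,
                          res$score > gain_threshold)
  res
}

#' Cluster marker discovery by three-way intersection
#'
#' Intersects (1) genes upregulated in a cluster versus all other cells,
#' (2) genes upregulated versus its sibling stem-like cluster, and (3)
#' genes located on a given chromosome arm. This is the procedure that
#' singles out an arm-linked cluster marker such as LAPTM4B on 8q.
#'
#' @param de_vs_rest,de_vs_sibling [diff_expr()] results over the same gene
#'   universe (`log2_fc` is the cluster relative to the comparison group).
#' @param loci Gene locus table (`gene`, `chrom`, `arm`).
#' @param arm Arm identifier, e.g. `"8q"`.
#' @param lfc_min,fdr_max Thresholds applied strictly (`log2_fc > lfc_min`,
#'   `fdr < fdr_max`); defaults 2 and 0.01.
#' @return List of class `marker_call` with the three input sets, the
#'   `markers` intersection (sorted), and the thresholds used. An empty
#'   intersection is a valid empty result.
#' @export
call_cluster_marker <- function(de_vs_rest, de_vs_sibling, loci, arm = "8q",
                                lfc_min = 2, fdr_max = 0.01) {
  if (nrow(de_vs_rest) == 0 || nrow(de_vs_sibling) == 0) {
    stop("empty gene universe")
  }
  if (!setequal(de_vs_rest$gene, de_vs_sibling$gene)) {
    stop("differential-expression tables cover different gene universes")
  }
  pass <- function(de) de$gene[de$log2_fc > lfc_min & de$fdr < fdr_max]
  up_rest <- pass(de_vs_rest)
  up_sib <- pass(de_vs_sibling)
  arm_genes <- loci$gene[paste0(loci$chrom, loci$arm) == arm]
  structure(
    list(up_vs_rest = sort(up_rest),
         up_vs_sibling = sort(up_sib),
         arm_genes = sort(arm_genes),
         markers = sort(intersect(intersect(up_rest, up_sib), arm_genes)),
         thresholds = c(lfc_min = lfc_min, fdr_max = fdr_max),
         arm = arm),
    class = "marker_call"
  )
}
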