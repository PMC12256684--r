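# Stem-like signature derivation, per-sample median scoring, four-way CSS
# quadrant assignment at cohort-median thresholds, and the combined
# two-marker recurrence score.

#' Construct a gene signature
#'
#' @param genes Ordered character vector, non-empty, no duplicates.
#' @param name Signature label.
#' @param provenance Optional record of the contrasts/thresholds that
#'   produced the signature.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(genes, name = "signature", provenance = NULL) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("signature must be non-empty")
  if (anyDuplicated(genes)) stop("signature contains duplicate genes")
  structure(list(name = name, genes = genes, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature>", x$name, "-", length(x$genes), "genes:",
      paste(utils::head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) "..." else "", "\n")
  invisible(x)
}

signature_genes <- function(x) {
  if (inherits(x, "gene_signature")) x$genes else as.character(x)
}

#' Core stem-like program gene sets
#'
#' The named core members of the two colorectal stem-like programs: the
#' LGR5-positive program (LGR5, OLFM4, TMEM19, TMEM238, CCL20) and the
#' LAPTM4B-positive program (LAPTM4B, TNNC2, EREG, C4orf48). These ship as
#' convenience defaults; full signatures are normally derived from data
#' with [build_signature()].
#'
#' @return List with `gene_signature` elements `lgr5` and `laptm4b`.
#' @export
default_signatures <- function() {
  list(
    lgr5 = gene_signature(c("LGR5", "OLFM4", "TMEM19", "TMEM238", "CCL20"),
                          name = "LGR5_stem"),
    laptm4b = gene_signature(c("LAPTM4B", "TNNC2", "EREG", "C4orf48"),
                             name = "LAPTM4B_stem")
  )
}

#' Derive a stem-like signature by contrast intersection
#'
#' A gene enters the signature when it is significantly upregulated in both
#' contrasts: (1) the malignant epithelial compartment versus other cells,
#' and (2) the stem-like subpopulation versus the other malignant epithelial
#' subpopulations. Genes are ordered by descending log2 fold change in the
#' within-epithelium contrast.
#'
#' @param de_epi_vs_other,de_sub_vs_subs [diff_expr()] results over the
#'   same gene universe.
#' @param lfc_min,fdr_max Strict thresholds (defaults 1 and 0.05).
#' @param name Signature label.
#' @return A [gene_signature()] with a provenance record.
#' @export
build_signature <- function(de_epi_vs_other, de_sub_vs_subs,
                            lfc_min = 1, fdr_max = 0.05, name = "signature") {
  if (!setequal(de_epi_vs_other$gene, de_sub_vs_subs$gene)) {
    stop("contrasts cover different gene universes")
  }
  pass <- function(de) de$gene[de$log2_fc > lfc_min & de$fdr < fdr_max]
  hits <- intersect(pass(de_epi_vs_other), pass(de_sub_vs_subs))
  if (length(hits) == 0) {
    stop("no genes pass both contrasts; consider relaxing lfc_min/fdr_max")
  }
  ord <- order(-de_sub_vs_subs$log2_fc[match(hits, de_sub_vs_subs$gene)])
  gene_signature(hits[ord], name = name,
                 provenance = list(lfc_min = lfc_min, fdr_max = fdr_max,
                                   n_pass_contrast1 = length(pass(de_epi_vs_other)),
                                   n_pass_contrast2 = length(pass(de_sub_vs_subs))))
}

#' Median signature score per sample
#'
#' The signature score of a sample is the median log-scale expression of
#' the signature genes present in the matrix. Missing genes are dropped
#' with a warning; fewer than `min_coverage` of the signature present is an
#' error.
#'
#' @param bulk Log-scale gene-by-sample matrix.
#' @param signature [gene_signature()] or character vector.
#' @param min_coverage Minimum fraction of signature genes that must be
#'   present (default 0.5).
#' @return Named numeric vector of per-sample scores.
#' @export
score_samples <- function(bulk, signature, min_coverage = 0.5) {
  bulk <- as.matrix(bulk)
  genes <- signature_genes(signature)
  present <- intersect(genes, rownames(bulk))
  if (length(present) < min_coverage * length(genes)) {
    stop("only ", length(present), "/", length(genes),
         " signature genes present; below the coverage floor of ",
         min_coverage)
  }
  missing <- setdiff(genes, present)
  if (length(missing)) {
    warning("signature genes absent from matrix and dropped: ",
            paste(missing, collapse = ", "))
  }
  apply(bulk[present, , drop = FALSE], 2L, stats::median)
}

#' Four-way stem-like subtype (CSS) assignment
#'
#' Each sample is called "high" on an axis when its signature score is
#' strictly greater than the cohort median of that score (the median
#' threshold suits the skewed score distributions; values tied with the
#' median count as "low", which keeps the all-constant case well defined).
#' Quadrants map to subtypes: low/low -> CSS1, LAPTM4B-dominant -> CSS2,
#' high/high -> CSS3, LGR5-dominant -> CSS4.
#'
#' @param scores_lgr5,scores_laptm4b Per-sample score vectors over the same
#'   samples (n >= 4), aligned by names when named.
#' @return `data.frame` with columns `sample`, `score_lgr5`,
#'   `score_laptm4b`, `subtype` (factor CSS1..CSS4); attribute `thresholds`
#'   holds the two cohort medians.
#' @export
assign_css <- function(scores_lgr5, scores_laptm4b) {
  if (!is.null(names(scores_lgr5)) && !is.null(names(scores_laptm4b))) {
    if (!setequal(names(scores_lgr5), names(scores_laptm4b))) {
      stop("score vectors cover different samples")
    }
    scores_laptm4b <- scores_laptm4b[names(scores_lgr5)]
  }
  if (length(scores_lgr5) != length(scores_laptm4b)) {
    stop("score vectors differ in length")
  }
  n <- length(scores_lgr5)
  if (n < 4) stop("at least 4 samples required")
  med_l <- stats::median(scores_lgr5)
  med_b <- stats::median(scores_laptm4b)
  high_l <- scores_lgr5 > med_l
  high_b <- scores_laptm4b > med_b
  subtype <- ifelse(!high_l & !high_b, "CSS1",
             ifelse(!high_l & high_b, "CSS2",
             ifelse(high_l & high_b, "CSS3", "CSS4")))
  ids <- names(scores_lgr5)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  out <- data.frame(
    sample = ids,
    score_lgr5 = unname(scores_lgr5),
    score_laptm4b = unname(scores_laptm4b),
    subtype = factor(subtype, levels = paste0("CSS", 1:4)),
    stringsAsFactors = FALSE
  )
  attr(out, "thresholds") <- c(median_lgr5 = med_l, median_laptm4b = med_b)
  out
}

#' Combined two-marker recurrence score
#'
#' Log-scale difference of LAPTM4B and LGR5 expression per sample — the
#' monotone (hence ROC-preserving) equivalent of the LAPTM4B/LGR5
#' expression ratio. Higher values predict higher recurrence risk.
#'
#' @param bulk Log-scale gene-by-sample matrix containing both genes.
#' @param laptm4b_gene,lgr5_gene Row names of the two markers.
#' @return Named numeric vector; attribute `direction` documents the
#'   positive class.
#' @export
combined_marker_score <- function(bulk, laptm4b_gene = "LAPTM4B",
                                  lgr5_gene = "LGR5") {
  bulk <- as.matrix(bulk)
  for (g in c(laptm4b_gene, lgr5_gene)) {
    if (!g %in% rownames(bulk)) stop("gene absent from matrix: ", g)
  }
  out <- bulk[laptm4b_gene, ] - bulk[lgr5_gene, ]
  attr(out, "direction") <- "higher score = higher predicted recurrence risk"
  out
}
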