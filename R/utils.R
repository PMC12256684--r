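# Shared helpers: seeded substreams and the normalization used upstream of
# differential expression and signature scoring.

# Deterministic sub-seed for a named random stream. Splitting the master seed
# per component keeps draws independent of unrelated config changes (e.g.
# regenerating survival times does not disturb the count draws).
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629)
}

with_substream <- function(seed, label, code) {
  withr::with_seed(substream_seed(seed, label), code)
}

#' Library-size normalization with log transform
#'
#' Scales every column (cell or sample) to a fixed total count
#' (counts-per-10k by default) and applies `log1p`. This is the transform
#' assumed by [diff_expr()] and by median signature scoring.
#'
#' @param counts Non-negative gene-by-unit count matrix with rownames.
#' @param scale_factor Target column total after scaling (default 1e4).
#' @return Matrix of the same shape on the log1p scale, flagged as
#'   log-normalized (attribute `lognorm`). Columns with zero total stay zero.
#' @export
normalize_log1p <- function(counts, scale_factor = 1e4) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  totals[totals == 0] <- 1
  out <- log1p(sweep(counts, 2L, totals / scale_factor, "/"))
  attr(out, "lognorm") <- TRUE
  out
}

is_lognorm <- function(x) isTRUE(attr(x, "lognorm"))

# Raw-count heuristic: all integer-valued with a large maximum. Used to catch
# matrices that skipped normalization.
looks_like_counts <- function(x) {
  v <- x[is.finite(x)]
  length(v) > 0 && max(v) > 30 && all(v == floor(v))
}

assert_lognorm <- function(x, what = "matrix") {
  if (is_lognorm(x)) return(invisible(TRUE))
  if (looks_like_counts(x)) {
    stop(what, " appears to contain raw counts; apply normalize_log1p() first")
  }
  invisible(TRUE)
}

#' Gene-wise centering and scaling within cohorts
#'
#' Standardizes every gene to zero mean and unit variance, separately within
#' each cohort, so signature scores from different cohorts share a scale
#' before median thresholding. Zero-variance genes are centered only.
#'
#' @param mat Gene-by-sample matrix (log scale).
#' @param cohort Optional per-sample cohort labels; `NULL` treats all samples
#'   as one cohort.
#' @return Matrix of the same shape, flagged as log-normalized.
#' @export
scale_within_cohort <- function(mat, cohort = NULL) {
  mat <- as.matrix(mat)
  if (is.null(cohort)) cohort <- rep("cohort1", ncol(mat))
  if (length(cohort) != ncol(mat)) stop("cohort labels must match columns")
  out <- mat
  for (co in unique(cohort)) {
    idx <- which(cohort == co)
    block <- mat[, idx, drop = FALSE]
    mu <- rowMeans(block)
    sdv <- apply(block, 1L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    out[, idx] <- (block - mu) / sdv
  }
  attr(out, "lognorm") <- TRUE
  out
}
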