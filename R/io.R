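# Readers and writers for the plain-text interchange formats: MatrixMarket
# MTX with gene/cell sidecars for single-cell counts, TSV for bulk
# matrices, loci, clinical and mutation tables. All coordinates in files
# are 1-based inclusive.

#' Read an expression matrix
#'
#' @param path MTX file (MatrixMarket coordinate format) or TSV file
#'   (genes x columns with a header; first column = gene id).
#' @param format `"mtx"` or `"tsv"`.
#' @param genes_path,cells_path Sidecar files for `"mtx"` (one id per
#'   line); default `<path>.genes.tsv` / `<path>.cells.tsv`.
#' @param values `"counts"` (non-negative; negative entries rejected with
#'   their location) or `"log"` (signed log-scale values, e.g. a
#'   batch-centered bulk matrix).
#' @return Dense numeric matrix with gene rownames and unit colnames.
#'   Duplicated gene ids are always rejected.
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            genes_path = NULL, cells_path = NULL,
                            values = c("counts", "log")) {
  format <- match.arg(format)
  values <- match.arg(values)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.tsv")
    if (is.null(cells_path)) cells_path <- paste0(path, ".cells.tsv")
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(cells_path)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    genes <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- genes
  }
  if (anyDuplicated(rownames(m))) {
    dups <- unique(rownames(m)[duplicated(rownames(m))])
    stop("duplicate gene ids: ", paste(dups, collapse = ", "))
  }
  if (values == "counts") {
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg) > 0) {
      stop("negative entry at gene ", rownames(m)[neg[1, 1]],
           ", column ", neg[1, 2])
    }
  }
  if (values == "log") attr(m, "lognorm") <- TRUE
  m
}

#' Write an expression matrix
#'
#' @param mat Matrix with dimnames.
#' @param path Output file.
#' @param format `"tsv"` (genes x columns with header) or `"mtx"`
#'   (MatrixMarket plus `<path>.genes.tsv` / `<path>.cells.tsv` sidecars).
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  mat <- as.matrix(mat)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
    writeLines(rownames(mat), paste0(path, ".genes.tsv"))
    writeLines(colnames(mat), paste0(path, ".cells.tsv"))
  } else {
    dt <- data.table::data.table(gene = rownames(mat))
    dt <- cbind(dt, data.table::as.data.table(mat))
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

#' Read a gene-locus table
#'
#' BED-like TSV with columns `gene`, `chrom`, `arm`, `start` (1-based).
#'
#' @param path TSV file.
#' @return `data.frame` with the four columns, validated.
#' @export
read_gene_loci <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("gene", "chrom", "arm", "start")
  if (!all(need %in% names(dt))) {
    stop("loci table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(dt$gene)) stop("duplicated genes in loci table")
  if (any(dt$start < 1)) stop("starts must be 1-based positive")
  if (!all(dt$arm %in% c("p", "q"))) stop("arm must be 'p' or 'q'")
  dt$chrom <- as.character(dt$chrom)
  dt[need]
}

#' Write a data frame as TSV
#'
#' @param df Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with at least `sample`, `time` (months), `event` (0/1); further
#' columns (msi, pole, stage, side, tmb, ...) pass through.
#'
#' @param path TSV file.
#' @return `data.frame`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("sample", "time", "event")
  if (!all(need %in% names(dt))) {
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(dt$event %in% c(0, 1))) stop("event must be 0/1")
  dt
}

#' Read a binary mutation table
#'
#' TSV, samples in the first column, genes in the remaining columns,
#' entries 0/1.
#'
#' @param path TSV file.
#' @return Binary sample-by-gene matrix.
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  if (!all(m %in% c(0, 1))) stop("mutation entries must be 0/1")
  m
}
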