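# Synthetic single-cell cohort generator. Emulates the structure the
# stratification analysis assumes: tumor and normal epithelial clusters with
# planted marker programs, one LGR5-type and one LAPTM4B-type stem-like
# cluster, the latter carrying a uniform expression gain on chromosome arm
# 8q and restricted to microsatellite-stable (MSS) patients.

#' Cluster specification for the single-cell simulator
#'
#' @param name Cluster label.
#' @param fraction Expected fraction of cells in this cluster.
#' @param marker_genes Genes whose negative-binomial mean is multiplied by
#'   `marker_fold` in this cluster.
#' @param marker_fold Fold change applied to marker genes (>= 1).
#' @param tissue `"tumor"` or `"normal"`; cells inherit the cluster tissue.
#' @param msi_restriction `"none"` or `"MSS-only"` (cells of this cluster
#'   are drawn only from MSS patients).
#' @return A `cluster_spec` list.
#' @export
cluster_spec <- function(name, fraction, marker_genes = character(),
                         marker_fold = 1, tissue = c("tumor", "normal"),
                         msi_restriction = c("none", "MSS-only")) {
  tissue <- match.arg(tissue)
  msi_restriction <- match.arg(msi_restriction)
  stopifnot(is.character(name), length(name) == 1L,
            fraction > 0, fraction <= 1, marker_fold >= 1)
  structure(
    list(name = name, fraction = fraction,
         marker_genes = as.character(marker_genes),
         marker_fold = marker_fold, tissue = tissue,
         msi_restriction = msi_restriction),
    class = "cluster_spec"
  )
}

#' Configuration for the single-cell simulator
#'
#' Counts are negative binomial with a shared dispersion: overdispersion is
#' the minimal realistic departure from Poisson for droplet scRNA-seq
#' counts. The 8q gain is a uniform multiplicative shift on the mean of
#' every 8q-assigned gene in the gain-bearing cluster — sufficient for the
#' expression-inferred arm-score detector downstream.
#'
#' @param n_genes,n_cells Gene and cell counts.
#' @param clusters List of [cluster_spec()]s; fractions must sum to 1 and
#'   marker lists must be disjoint.
#' @param baseline_mean Negative-binomial mean per gene per cell.
#' @param nb_dispersion Shared NB dispersion (variance `mu + phi*mu^2`).
#' @param frac_8q_genes Fraction of genes assigned to chromosome arm 8q
#'   (`n_genes * frac_8q_genes >= 50`).
#' @param arm_gain_factor Multiplier applied to all 8q genes in
#'   `gain_cluster` (>= 1; 1 disables the gain).
#' @param gain_cluster Name of the gain-bearing cluster (`NULL` for none).
#' @param n_patients,msi_fraction Patient pool size and fraction of MSI
#'   patients.
#' @param seed Master seed; all randomness flows from it through named
#'   substreams.
#' @return An `sc_sim_config` list.
#' @export
sc_sim_config <- function(n_genes, n_cells, clusters, baseline_mean = 0.5,
                          nb_dispersion = 0.5, frac_8q_genes = 0.1,
                          arm_gain_factor = 2, gain_cluster = NULL,
                          n_patients = 12, msi_fraction = 0.25, seed = 1L) {
  stopifnot(n_genes >= 1, n_cells >= 1, baseline_mean > 0, nb_dispersion > 0,
            frac_8q_genes > 0, frac_8q_genes < 1, arm_gain_factor >= 1,
            n_patients >= 2, msi_fraction > 0, msi_fraction < 1)
  fr <- vapply(clusters, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) stop("cluster fractions must sum to 1")
  if (round(n_genes * frac_8q_genes) < 50) {
    stop("n_genes * frac_8q_genes must be at least 50")
  }
  marker_lists <- lapply(clusters, `[[`, "marker_genes")
  all_markers <- unlist(marker_lists)
  if (anyDuplicated(all_markers)) {
    stop("marker gene lists must be disjoint across clusters")
  }
  if (length(all_markers) > n_genes) {
    stop("marker lists reference more genes than n_genes")
  }
  cl_names <- vapply(clusters, `[[`, character(1), "name")
  if (anyDuplicated(cl_names)) stop("cluster names must be unique")
  names(clusters) <- cl_names
  if (!is.null(gain_cluster) && !gain_cluster %in% cl_names) {
    stop("gain_cluster not among cluster names")
  }
  structure(
    list(n_genes = n_genes, n_cells = n_cells, clusters = clusters,
         baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
         frac_8q_genes = frac_8q_genes, arm_gain_factor = arm_gain_factor,
         gain_cluster = gain_cluster, n_patients = n_patients,
         msi_fraction = msi_fraction, seed = as.integer(seed)),
    class = "sc_sim_config"
  )
}

#' Default single-cell study conditions
#'
#' Two stem-like tumor clusters (an LGR5-type cluster with a 30-gene
#' program at 6-fold, and an MSS-restricted LAPTM4B-type cluster with 5
#' planted 8q markers at 4-fold on top of a 2-fold arm-wide 8q gain), two
#' non-stem tumor epithelial clusters, and two normal epithelial clusters;
#' 2,000 genes, 3,000 cells.
#'
#' @param seed Master seed.
#' @param n_cells,n_genes Override the dataset size.
#' @return An [sc_sim_config()].
#' @export
default_sc_config <- function(seed = 1L, n_cells = 3000, n_genes = 2000) {
  lgr5_prog <- c("LGR5", "OLFM4", "TMEM19", "TMEM238", "CCL20",
                 sprintf("LGR5P%02d", 6:30))
  laptm4b_prog <- c("LAPTM4B", "MYC", "TNNC2", "EREG", "C4orf48")
  clusters <- list(
    cluster_spec("stem_lgr5", 0.20, lgr5_prog, 6, "tumor"),
    cluster_spec("stem_laptm4b", 0.12, laptm4b_prog, 4, "tumor", "MSS-only"),
    cluster_spec("epi_prolif", 0.23, sprintf("PRF%02d", 1:20), 4, "tumor"),
    cluster_spec("epi_mucin", 0.15, sprintf("MUC%02d", 1:20), 4, "tumor"),
    cluster_spec("ent_normal", 0.18, sprintf("ENT%02d", 1:20), 4, "normal"),
    cluster_spec("gob_normal", 0.12, sprintf("GOB%02d", 1:20), 4, "normal")
  )
  sc_sim_config(n_genes = n_genes, n_cells = n_cells, clusters = clusters,
                gain_cluster = "stem_laptm4b", seed = seed)
}

#' Null single-cell configuration
#'
#' Same layout as [default_sc_config()] but with every marker fold and the
#' arm gain set to 1, so all clusters share one expression distribution.
#' Used to calibrate noise floors.
#'
#' @inheritParams default_sc_config
#' @return An [sc_sim_config()].
#' @export
null_sc_config <- function(seed = 1L, n_cells = 500, n_genes = 2000) {
  cfg <- default_sc_config(seed = seed, n_cells = n_cells, n_genes = n_genes)
  cfg$clusters <- lapply(cfg$clusters, function(cl) {
    cl$marker_fold <- 1
    cl
  })
  cfg$arm_gain_factor <- 1
  cfg
}

# Synthetic gene loci: the gain cluster's markers are forced onto 8q, every
# other cluster's markers are kept off 8q, the remaining 8q slots are filled
# at random, and leftover genes are spread over the other chromosome arms.
build_loci <- function(cfg, genes) {
  n8q <- round(cfg$n_genes * cfg$frac_8q_genes)
  force_8q <- if (!is.null(cfg$gain_cluster)) {
    cfg$clusters[[cfg$gain_cluster]]$marker_genes
  } else character()
  other_markers <- setdiff(
    unlist(lapply(cfg$clusters, `[[`, "marker_genes")), force_8q)
  pool <- setdiff(genes, c(force_8q, other_markers))
  if (length(force_8q) > n8q) stop("more forced 8q markers than 8q slots")
  fill <- with_substream(cfg$seed, "loci",
                         sample(pool, n8q - length(force_8q)))
  genes_8q <- c(force_8q, fill)
  rest <- setdiff(genes, genes_8q)
  arms <- c(outer(setdiff(1:22, 8), c("p", "q"), paste0), "8p")
  arm_of <- rep(arms, length.out = length(rest))
  loci <- data.frame(
    gene = c(genes_8q, rest),
    chrom = c(rep("8", length(genes_8q)),
              sub("[pq]$", "", arm_of)),
    arm = c(rep("q", length(genes_8q)), sub("^[0-9]+", "", arm_of)),
    stringsAsFactors = FALSE
  )
  # distinct 1-based starts within each arm
  loci <- loci[order(as.integer(loci$chrom), loci$arm, loci$gene), ]
  loci$start <- stats::ave(seq_len(nrow(loci)),
                           paste(loci$chrom, loci$arm),
                           FUN = seq_along) * 100000L + 1L
  rownames(loci) <- NULL
  loci
}

#' Simulate a single-cell expression cohort
#'
#' Draws negative-binomial counts under the configured cluster structure and
#' returns the count matrix, per-cell annotation, a synthetic gene-locus
#' table, and a planted-truth record. Identical config and seed give
#' bit-identical output.
#'
#' @param config An [sc_sim_config()].
#' @return List of class `sc_sim` with elements `counts` (genes x cells),
#'   `cells` (cell, patient, tissue, cluster, msi, side), `loci`
#'   (gene, chrom, arm, start) and `truth`.
#' @export
simulate_sc <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  cfg <- config
  all_markers <- unlist(lapply(cfg$clusters, `[[`, "marker_genes"))
  n_fill <- cfg$n_genes - length(all_markers)
  genes <- c(all_markers, sprintf("g%05d", seq_len(n_fill)))
  loci <- build_loci(cfg, genes)
  genes_8q <- loci$gene[loci$chrom == "8" & loci$arm == "q"]

  # patients: fixed MSI split, alternating tumor side
  n_msi <- max(1L, round(cfg$n_patients * cfg$msi_fraction))
  patients <- data.frame(
    patient = sprintf("P%02d", seq_len(cfg$n_patients)),
    msi = rep(c("MSI", "MSS"),
              c(n_msi, cfg$n_patients - n_msi)),
    side = rep_len(c("left", "right"), cfg$n_patients),
    stringsAsFactors = FALSE
  )

  cl_names <- names(cfg$clusters)
  fr <- vapply(cfg$clusters, `[[`, numeric(1), "fraction")
  cells <- with_substream(cfg$seed, "cells", {
    cl <- sample(cl_names, cfg$n_cells, replace = TRUE, prob = fr)
    pat <- character(cfg$n_cells)
    mss_pat <- patients$patient[patients$msi == "MSS"]
    for (i in seq_len(cfg$n_cells)) {
      pool <- if (cfg$clusters[[cl[i]]]$msi_restriction == "MSS-only") {
        mss_pat
      } else {
        patients$patient
      }
      pat[i] <- pool[sample.int(length(pool), 1L)]
    }
    data.frame(
      cell = sprintf("c%05d", seq_len(cfg$n_cells)),
      patient = pat,
      tissue = vapply(cl, function(x) cfg$clusters[[x]]$tissue, character(1)),
      cluster = cl,
      msi = patients$msi[match(pat, patients$patient)],
      side = patients$side[match(pat, patients$patient)],
      stringsAsFactors = FALSE
    )
  })

  # per-cluster mean vectors
  mu_by_cluster <- matrix(cfg$baseline_mean, nrow = cfg$n_genes,
                          ncol = length(cl_names),
                          dimnames = list(genes, cl_names))
  for (cl in cfg$clusters) {
    if (length(cl$marker_genes) && cl$marker_fold != 1) {
      mu_by_cluster[cl$marker_genes, cl$name] <-
        mu_by_cluster[cl$marker_genes, cl$name] * cl$marker_fold
    }
  }
  if (!is.null(cfg$gain_cluster) && cfg$arm_gain_factor != 1) {
    mu_by_cluster[genes_8q, cfg$gain_cluster] <-
      mu_by_cluster[genes_8q, cfg$gain_cluster] * cfg$arm_gain_factor
  }

  mu <- mu_by_cluster[, match(cells$cluster, cl_names), drop = FALSE]
  counts <- with_substream(cfg$seed, "counts", {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
           nrow = cfg$n_genes,
           dimnames = list(genes, cells$cell))
  })

  truth <- list(
    cluster = stats::setNames(cells$cluster, cells$cell),
    markers = stats::setNames(lapply(cfg$clusters, `[[`, "marker_genes"),
                              cl_names),
    gain_cluster = cfg$gain_cluster,
    arm_gain_factor = cfg$arm_gain_factor,
    genes_8q = genes_8q,
    config = cfg
  )
  structure(list(counts = counts, cells = cells, loci = loci, truth = truth),
            class = "sc_sim")
}
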