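# Synthetic bulk cohort generator: four planted subtype profiles mixing the
# LGR5-type and LAPTM4B-type programs into log-scale expression, exponential
# survival with subtype-specific hazards, subtype-dependent mutation
# frequencies and mutational burden, and clinical covariates.

#' Survival component of the bulk simulator
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hr[subtype])`; censoring is administrative at
#' `horizon_months` plus, with probability `censor_rate`, an additional
#' uniform censoring time on `(0, horizon_months)`.
#'
#' @param baseline_hazard Events per month for the reference subtype.
#' @param log_hr_per_subtype Named length-4 numeric (CSS1..CSS4) of log
#'   hazard ratios; the reference subtype has 0.
#' @param censor_rate Probability of extra uniform censoring, in `[0, 1)`.
#' @param horizon_months Administrative censoring horizon (> 0).
#' @return A `surv_sim_spec` list.
#' @export
surv_sim_spec <- function(baseline_hazard = 0.006,
                          log_hr_per_subtype = c(CSS1 = log(1.5),
                                                 CSS2 = log(2.31),
                                                 CSS3 = log(1.5),
                                                 CSS4 = 0),
                          censor_rate = 0.2, horizon_months = 60) {
  stopifnot(baseline_hazard > 0, length(log_hr_per_subtype) == 4,
            censor_rate >= 0, censor_rate < 1, horizon_months > 0)
  if (is.null(names(log_hr_per_subtype))) {
    names(log_hr_per_subtype) <- paste0("CSS", 1:4)
  }
  structure(list(baseline_hazard = baseline_hazard,
                 log_hr_per_subtype = log_hr_per_subtype,
                 censor_rate = censor_rate,
                 horizon_months = horizon_months),
            class = "surv_sim_spec")
}

#' Configuration for the bulk cohort simulator
#'
#' Each sample is drawn from one of four planted profiles on the log
#' expression scale: CSS1 adds neither program, CSS2 adds the LAPTM4B
#' program, CSS3 adds both, CSS4 adds the LGR5 program. Gaussian noise is
#' added per gene per sample.
#'
#' @param n_samples Number of samples.
#' @param subtype_proportions Length-4 fractions (CSS1..CSS4) summing to 1.
#' @param lgr5_program,laptm4b_program Named numeric vectors of log-scale
#'   effect sizes per program gene (a bare character vector gets effect 1).
#' @param noise_sd Gaussian noise standard deviation (log scale).
#' @param survival A [surv_sim_spec()].
#' @param mutation_freqs Gene-by-subtype matrix of Bernoulli mutation
#'   probabilities (4 columns, CSS1..CSS4).
#' @param tmb_mean,tmb_size Per-subtype negative-binomial mean and size for
#'   the simulated mutational burden.
#' @param msi_prob,pole_prob,left_prob Per-subtype probabilities of MSI
#'   status, POLE mutation, and left-sided location.
#' @param n_genes Number of background (non-program) genes.
#' @param seed Master seed.
#' @return A `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(n_samples,
                            subtype_proportions = rep(0.25, 4),
                            lgr5_program,
                            laptm4b_program,
                            noise_sd = 0.5,
                            survival = surv_sim_spec(),
                            mutation_freqs = default_mutation_freqs(),
                            tmb_mean = c(40, 10, 10, 10),
                            tmb_size = 5,
                            msi_prob = c(0.5, 0.05, 0.05, 0.05),
                            pole_prob = c(0.15, 0.02, 0.02, 0.02),
                            left_prob = c(0.35, 0.67, 0.5, 0.73),
                            n_genes = 1000, seed = 1L) {
  as_program <- function(p) {
    if (is.character(p)) p <- stats::setNames(rep(1, length(p)), p)
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      stop("program effect vectors must be named by gene")
    }
    p
  }
  lgr5_program <- as_program(lgr5_program)
  laptm4b_program <- as_program(laptm4b_program)
  if (length(lgr5_program) == 0 || length(laptm4b_program) == 0) {
    stop("both programs must be non-empty")
  }
  if (abs(sum(subtype_proportions) - 1) > 1e-9) {
    stop("subtype_proportions must sum to 1")
  }
  stopifnot(all(subtype_proportions >= 0), noise_sd > 0,
            inherits(survival, "surv_sim_spec"),
            all(mutation_freqs >= 0 & mutation_freqs <= 1),
            ncol(mutation_freqs) == 4,
            all(msi_prob >= 0 & msi_prob <= 1),
            all(pole_prob >= 0 & pole_prob <= 1),
            all(left_prob >= 0 & left_prob <= 1),
            all(tmb_mean > 0), tmb_size > 0, n_samples >= 4, n_genes >= 1)
  structure(
    list(n_samples = as.integer(n_samples),
         subtype_proportions = subtype_proportions,
         lgr5_program = lgr5_program, laptm4b_program = laptm4b_program,
         noise_sd = noise_sd, survival = survival,
         mutation_freqs = mutation_freqs,
         tmb_mean = tmb_mean, tmb_size = tmb_size,
         msi_prob = msi_prob, pole_prob = pole_prob, left_prob = left_prob,
         n_genes = as.integer(n_genes), seed = as.integer(seed)),
    class = "bulk_sim_config"
  )
}

#' Default per-subtype mutation frequencies
#'
#' Gene-by-subtype Bernoulli probabilities for five recurrently mutated
#' colorectal genes, reflecting the reported pattern: APC highest in the
#' LGR5-enriched subtypes (0.84 / 0.78 in CSS3 / CSS4), TP53 highest (0.75)
#' in the LAPTM4B-dominant CSS2, BRAF concentrated in the MSI-enriched CSS1.
#'
#' @return Matrix genes x CSS1..CSS4.
#' @export
default_mutation_freqs <- function() {
  m <- rbind(
    TP53   = c(0.40, 0.75, 0.60, 0.40),
    APC    = c(0.50, 0.60, 0.84, 0.78),
    KRAS   = c(0.40, 0.45, 0.45, 0.40),
    BRAF   = c(0.35, 0.05, 0.05, 0.05),
    PIK3CA = c(0.30, 0.25, 0.30, 0.25)
  )
  colnames(m) <- paste0("CSS", 1:4)
  m
}

#' Default bulk study conditions
#'
#' 400 samples in four equal subtypes; programs default to the planted
#' single-cell programs of [default_sc_config()] with unit log-scale effect.
#'
#' @param n_samples Cohort size.
#' @param seed Master seed.
#' @return A [bulk_sim_config()].
#' @export
default_bulk_config <- function(n_samples = 400, seed = 1L) {
  bulk_sim_config(
    n_samples = n_samples,
    lgr5_program = c("LGR5", "OLFM4", "TMEM19", "TMEM238", "CCL20",
                     sprintf("LGR5P%02d", 6:30)),
    laptm4b_program = c("LAPTM4B", "MYC", "TNNC2", "EREG", "C4orf48"),
    seed = seed
  )
}

#' Simulate a bulk expression cohort with outcomes
#'
#' @param config A [bulk_sim_config()].
#' @param signatures Optional list with elements `lgr5` and `laptm4b`
#'   (character vectors or `gene_signature`s) overriding the program gene
#'   lists (effects default to 1).
#' @return List of class `bulk_sim` with `expr` (genes x samples, log
#'   scale, flagged log-normalized), `clinical` (sample, time, event, msi,
#'   pole, stage, side, tmb), `mutations` (samples x genes binary matrix)
#'   and `subtype` (planted labels, named by sample).
#' @export
simulate_bulk <- function(config, signatures = NULL) {
  stopifnot(inherits(config, "bulk_sim_config"))
  cfg <- config
  if (!is.null(signatures)) {
    cfg$lgr5_program <- stats::setNames(
      rep(1, length(signature_genes(signatures$lgr5))),
      signature_genes(signatures$lgr5))
    cfg$laptm4b_program <- stats::setNames(
      rep(1, length(signature_genes(signatures$laptm4b))),
      signature_genes(signatures$laptm4b))
    if (length(cfg$lgr5_program) == 0 || length(cfg$laptm4b_program) == 0) {
      stop("both signatures must be non-empty")
    }
  }
  prog_genes <- union(names(cfg$lgr5_program), names(cfg$laptm4b_program))
  genes <- c(prog_genes, sprintf("bg%05d", seq_len(cfg$n_genes)))
  n <- cfg$n_samples
  samples <- sprintf("s%04d", seq_len(n))
  subtype_levels <- paste0("CSS", 1:4)

  subtype <- with_substream(cfg$seed, "bulk-subtypes", {
    factor(sample(subtype_levels, n, replace = TRUE,
                  prob = cfg$subtype_proportions), levels = subtype_levels)
  })

  baseline <- with_substream(cfg$seed, "bulk-baseline", {
    stats::setNames(stats::rnorm(length(genes), mean = 5, sd = 1), genes)
  })

  effect <- matrix(0, nrow = length(genes), ncol = 4,
                   dimnames = list(genes, subtype_levels))
  effect[names(cfg$laptm4b_program), "CSS2"] <-
    effect[names(cfg$laptm4b_program), "CSS2"] + cfg$laptm4b_program
  effect[names(cfg$laptm4b_program), "CSS3"] <-
    effect[names(cfg$laptm4b_program), "CSS3"] + cfg$laptm4b_program
  effect[names(cfg$lgr5_program), "CSS3"] <-
    effect[names(cfg$lgr5_program), "CSS3"] + cfg$lgr5_program
  effect[names(cfg$lgr5_program), "CSS4"] <-
    effect[names(cfg$lgr5_program), "CSS4"] + cfg$lgr5_program

  expr <- with_substream(cfg$seed, "bulk-expr", {
    mu <- baseline + effect[, as.integer(subtype), drop = FALSE]
    mu + matrix(stats::rnorm(length(genes) * n, sd = cfg$noise_sd),
                nrow = length(genes))
  })
  dimnames(expr) <- list(genes, samples)
  attr(expr, "lognorm") <- TRUE

  sv <- cfg$survival
  surv <- with_substream(cfg$seed, "bulk-survival", {
    rate <- sv$baseline_hazard * exp(sv$log_hr_per_subtype[as.integer(subtype)])
    t_event <- stats::rexp(n, rate)
    cens <- rep(sv$horizon_months, n)
    extra <- stats::runif(n) < sv$censor_rate
    cens[extra] <- pmin(cens[extra],
                        stats::runif(sum(extra), 0, sv$horizon_months))
    data.frame(time = pmin(t_event, cens),
               event = as.integer(t_event <= cens))
  })

  clinical <- with_substream(cfg$seed, "bulk-clinical", {
    k <- as.integer(subtype)
    data.frame(
      sample = samples,
      time = surv$time,
      event = surv$event,
      msi = ifelse(stats::runif(n) < cfg$msi_prob[k], "MSI", "MSS"),
      pole = ifelse(stats::runif(n) < cfg$pole_prob[k], "mutant", "wildtype"),
      stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                     prob = c(0.15, 0.35, 0.35, 0.15)),
      side = ifelse(stats::runif(n) < cfg$left_prob[k], "left", "right"),
      stringsAsFactors = FALSE
    )
  })

  mut <- with_substream(cfg$seed, "bulk-mutations", {
    k <- as.integer(subtype)
    m <- vapply(rownames(cfg$mutation_freqs), function(g) {
      as.integer(stats::runif(n) < cfg$mutation_freqs[g, k])
    }, integer(n))
    rownames(m) <- samples
    m
  })
  clinical$tmb <- with_substream(cfg$seed, "bulk-tmb", {
    stats::rnbinom(n, mu = cfg$tmb_mean[as.integer(subtype)],
                   size = cfg$tmb_size)
  })

  structure(
    list(expr = expr, clinical = clinical, mutations = mut,
         subtype = stats::setNames(as.character(subtype), samples),
         config = cfg),
    class = "bulk_sim"
  )
}
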