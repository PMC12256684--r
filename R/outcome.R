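# Survival and association statistics: Kaplan-Meier, log-rank, Cox
# proportional hazards (Breslow ties), ROC/AUC via the rank identity,
# per-gene Fisher mutation enrichment with BH control, and Welch t
# comparisons of mutational burden.

check_surv <- function(time, event) {
  if (length(time) == 0) stop("no survival records")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be positive")
  }
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  invisible(TRUE)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function, optionally stratified
#' by group, with the number at risk and events at every event time.
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Optional per-record group labels.
#' @return `data.frame` with columns `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (non-increasing within group, starting at 1).
#' @export
km_estimate <- function(time, event, group = NULL) {
  check_surv(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  fit <- survival::survfit(
    survival::Surv(time, event) ~ grp,
    data = data.frame(time = time, event = event, grp = group)
  )
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(group)[1], length(s$time)) else {
    sub("^grp=", "", as.character(s$strata))
  }
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, n_censor = s$n.censor, surv = s$surv,
             stringsAsFactors = FALSE)
}

#' Two-or-more-group log-rank test
#'
#' @inheritParams km_estimate
#' @param group Group labels; every group must be non-empty and at least
#'   one event must be observed overall.
#' @return List with `statistic` (chi-square), `df`, and `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  group <- as.character(group)
  tab <- table(group)
  if (length(tab) < 2) stop("need at least two non-empty groups")
  if (any(tab == 0)) stop("empty group in log-rank test")
  if (sum(event) == 0) stop("no events observed; log-rank test undefined")
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ grp,
    data = data.frame(time = time, event = event, grp = group)
  )
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional hazards fit (Breslow ties)
#'
#' Partial-likelihood Cox regression via `survival::coxph` with the
#' Breslow tie approximation; reports hazard ratios with Wald 95%
#' confidence intervals and p-values.
#'
#' @inheritParams km_estimate
#' @param covariates Data frame of covariates (numeric or factor), one row
#'   per record; no covariate may be constant, and the number of events
#'   must exceed the number of fitted coefficients.
#' @return `data.frame` with columns `term`, `coef`, `hr`, `ci_lower`,
#'   `ci_upper`, `p_value`, plus attributes `n` and `n_events`.
#' @export
cox_fit <- function(time, event, covariates) {
  check_surv(time, event)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(time)) stop("covariate rows must match records")
  for (nm in names(covariates)) {
    if (length(unique(covariates[[nm]])) < 2) {
      stop("covariate is constant: ", nm)
    }
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = dat, ties = "breslow")
  if (sum(event) < length(stats::coef(fit)) + 1) {
    stop("too few events for the number of coefficients")
  }
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (anyNA(co) || any(!is.finite(se)) || any(abs(co) > 15)) {
    stop("Cox fit did not converge (possible separation); coefficients: ",
         paste(sprintf("%s=%.3g", names(co), co), collapse = ", "))
  }
  z <- co / se
  out <- data.frame(
    term = names(co), coef = unname(co), hr = exp(unname(co)),
    ci_lower = exp(unname(co - 1.96 * se)),
    ci_upper = exp(unname(co + 1.96 * se)),
    p_value = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )
  attr(out, "n") <- length(time)
  attr(out, "n_events") <- sum(event)
  out
}

#' ROC curve and AUC via the rank (Mann-Whitney) identity
#'
#' AUC is computed from mid-ranks, so tied score pairs count one half; this
#' equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric predictor; higher values predict the positive
#'   class.
#' @param labels Binary outcome (0/1 or logical); both classes must occur.
#' @return List with `auc`, `roc` (`data.frame` of `threshold`, `fpr`,
#'   `tpr`), and `direction`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, roc = roc,
       direction = "higher scores predict the positive class")
}

#' Per-gene mutation enrichment between two groups
#'
#' Two-sided Fisher's exact test on the 2x2 table (mutated/wild-type by
#' group) for every gene, with Benjamini-Hochberg correction across genes.
#'
#' @param mutations Binary sample-by-gene matrix (0/1).
#' @param groups Per-sample group labels.
#' @param pair Length-2 vector naming the two groups to compare (defaults
#'   to the first two levels).
#' @return `data.frame` with per-gene mutation counts and frequencies in
#'   each group, the conditional odds-ratio estimate, `p_value`, and BH
#'   `q_value`.
#' @export
mutation_enrichment <- function(mutations, groups, pair = NULL) {
  mutations <- as.matrix(mutations)
  if (!all(mutations %in% c(0, 1))) stop("mutation matrix must be binary")
  groups <- as.character(groups)
  if (length(groups) != nrow(mutations)) {
    stop("group labels must match mutation rows")
  }
  if (is.null(pair)) pair <- utils::head(unique(groups), 2)
  if (length(pair) != 2) stop("pair must name two groups")
  ia <- groups == pair[1]
  ib <- groups == pair[2]
  if (sum(ia) == 0 || sum(ib) == 0) stop("a compared group has zero samples")
  res <- lapply(colnames(mutations), function(g) {
    ma <- sum(mutations[ia, g])
    mb <- sum(mutations[ib, g])
    tab <- matrix(c(ma, sum(ia) - ma, mb, sum(ib) - mb), nrow = 2)
    ft <- stats::fisher.test(tab)
    data.frame(gene = g, n_mut_a = ma, n_a = sum(ia), n_mut_b = mb,
               n_b = sum(ib), freq_a = ma / sum(ia), freq_b = mb / sum(ib),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "pair") <- pair
  out
}

#' Pairwise mutational-burden comparison
#'
#' Welch two-sided t-tests on per-sample mutation counts for every pair of
#' groups. A zero-variance pair with equal means is reported as t = 0,
#' p = 1 by convention.
#'
#' @param tmb Per-sample non-negative mutation counts.
#' @param groups Per-sample group labels; every compared group needs
#'   n >= 3.
#' @return `data.frame` with columns `group_a`, `group_b`, `mean_a`,
#'   `mean_b`, `t`, `p_value`.
#' @export
tmb_compare <- function(tmb, groups) {
  groups <- as.character(groups)
  if (length(tmb) != length(groups)) stop("tmb and groups differ in length")
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least two groups")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- lapply(pairs, function(p) {
    a <- tmb[groups == p[1]]
    b <- tmb[groups == p[2]]
    if (length(a) < 3 || length(b) < 3) {
      stop("group with fewer than 3 samples: ", p[1], " vs ", p[2])
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) {
        message("zero-variance pair with equal means (", p[1], " vs ", p[2],
                "); p set to 1")
        return(data.frame(group_a = p[1], group_b = p[2], mean_a = mean(a),
                          mean_b = mean(b), t = 0, p_value = 1,
                          stringsAsFactors = FALSE))
      }
      stop("zero variance in both groups with unequal means: ",
           p[1], " vs ", p[2])
    }
    tt <- stats::t.test(a, b)
    data.frame(group_a = p[1], group_b = p[2], mean_a = mean(a),
               mean_b = mean(b), t = unname(tt$statistic),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
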