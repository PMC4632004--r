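# Master-regulator compound scores, binary activation, three-group
# prognostic stratification, and survival summaries (Kaplan-Meier,
# log-rank, proportional-hazards fits, pooled meta-analysis, paired
# comparisons, score-gene correlation). Survival estimation is delegated to
# the survival package behind this module's interface.

#' Per-sample master-regulator compound scores
#'
#' ssGSEA scores of the mesenchymal and immunoreactive MR gene sets for
#' every sample; activation booleans and prognostic groups are added later
#' by [dichotomize()] and [stratify()].
#'
#' @param X An [expression_matrix()].
#' @param mese_mrs,immu_mrs [gene_set()] objects (MR symbol lists).
#' @param alpha ssGSEA exponent.
#' @param min_overlap Minimum genes shared between a set and the matrix.
#' @return Data.frame: sample_id, dataset_id, mese_raw, immu_raw,
#'   mese_norm, immu_norm (NA until normalized).
#' @export
compound_scores <- function(X, mese_mrs, immu_mrs, alpha = 0.25, min_overlap = 3L) {
  m <- ssgsea(X, mese_mrs, alpha = alpha, min_overlap = min_overlap)
  i <- ssgsea(X, immu_mrs, alpha = alpha, min_overlap = min_overlap)
  data.frame(sample_id = m$sample_id, dataset_id = m$dataset_id,
             mese_raw = m$raw, immu_raw = i$raw,
             mese_norm = NA_real_, immu_norm = NA_real_,
             stringsAsFactors = FALSE)
}

#' Median dichotomization of scores
#'
#' High activation means the score is strictly above the within-dataset
#' median (a score equal to the median is low, so at most ceiling(n/2)
#' samples can be high). For even n the median is the mean of the two
#' central order statistics.
#'
#' @param scores Numeric vector.
#' @param dataset Optional dataset labels; the median is taken within each.
#' @return Logical vector (TRUE = high).
#' @export
dichotomize <- function(scores, dataset = NULL) {
  if (is.null(dataset)) dataset <- rep("all", length(scores))
  out <- logical(length(scores))
  for (ds in unique(dataset)) {
    idx <- dataset == ds
    if (sum(idx) < 2L) stop("dataset '", ds, "' has fewer than 2 samples")
    s <- scores[idx]
    if (max(s) == min(s)) stop("dataset '", ds, "' has all-equal scores")
    out[idx] <- s > stats::median(s)
  }
  out
}

#' Three-group prognostic stratification from activation booleans
#'
#' immu-high/mese-low -> "immu+mese-"; immu-low/mese-high -> "immu-mese+";
#' both or neither -> "mixed". The four-way subgroup (immu+mese+,
#' immu-mese-, and the two pure groups) is retained for the
#' both-active-vs-immu-only contrast.
#'
#' @param mese_active,immu_active Logical vectors.
#' @return Data.frame: group, subgroup (factors).
#' @export
stratify <- function(mese_active, immu_active) {
  if (length(mese_active) != length(immu_active))
    stop("activation vectors must have equal length")
  subgroup <- ifelse(immu_active,
                     ifelse(mese_active, "immu+mese+", "immu+mese-"),
                     ifelse(mese_active, "immu-mese+", "immu-mese-"))
  group <- ifelse(subgroup == "immu+mese-", "immu+mese-",
                  ifelse(subgroup == "immu-mese+", "immu-mese+", "mixed"))
  data.frame(group = factor(group, levels = c("immu+mese-", "mixed", "immu-mese+")),
             subgroup = factor(subgroup, levels = c("immu+mese-", "immu+mese+",
                                                    "immu-mese-", "immu-mese+")),
             stringsAsFactors = FALSE)
}

#' Score, normalize, dichotomize and stratify one cohort
#'
#' Convenience composition: [compound_scores()] then per-dataset
#' normalization, median dichotomization of the raw scores, and
#' [stratify()].
#'
#' @inheritParams compound_scores
#' @return The compound-score table with mese_active, immu_active, group,
#'   subgroup columns appended.
#' @export
score_and_stratify <- function(X, mese_mrs, immu_mrs, alpha = 0.25) {
  sc <- compound_scores(X, mese_mrs, immu_mrs, alpha = alpha)
  sc$mese_norm <- normalize_scores(data.frame(raw = sc$mese_raw, normalized = NA_real_,
                                              dataset_id = sc$dataset_id))$normalized
  sc$immu_norm <- normalize_scores(data.frame(raw = sc$immu_raw, normalized = NA_real_,
                                              dataset_id = sc$dataset_id))$normalized
  sc$mese_active <- dichotomize(sc$mese_raw, sc$dataset_id)
  sc$immu_active <- dichotomize(sc$immu_raw, sc$dataset_id)
  cbind(sc, stratify(sc$mese_active, sc$immu_active))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator; censored subjects leave the risk set after
#' their time.
#'
#' @param times Non-negative times (months).
#' @param events 0/1 event indicators; at least one event required.
#' @return Data.frame step function: time, n_risk, n_event, n_censor, surv;
#'   attribute `median` holds the median survival time (NA if the curve
#'   never reaches 0.5).
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty input")
  if (sum(events) < 1) stop("need at least one observed event")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  med <- unname(summary(fit)$table["median"])
  attr(out, "median") <- med
  out
}

#' Multi-group log-rank test
#'
#' @param times,events Survival data.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List: chi2, df, p.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(as.vector(groups))
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("log-rank needs >= 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Univariate proportional-hazards fit
#'
#' Cox partial likelihood with Efron tie handling; HR = exp(beta) with Wald
#' confidence interval and p-value.
#'
#' @param times,events Survival data.
#' @param covariate Numeric covariate (non-constant).
#' @param conf_level Confidence level (default 0.95).
#' @return List: hr, ci_low, ci_high, p, beta, se.
#' @export
hazard_ratio <- function(times, events, covariate, conf_level = 0.95) {
  if (length(unique(covariate)) == 1L) stop("covariate is constant")
  fit <- survival::coxph(survival::Surv(times, events) ~ covariate, ties = "efron")
  beta <- unname(stats::coef(fit))
  if (!is.finite(beta)) stop("proportional-hazards fit did not converge")
  se <- sqrt(unname(fit$var[1, 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(-abs(beta / se))
  list(hr = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
       p = p, beta = beta, se = se)
}

#' Per-gene hazard-ratio table (forest-plot data)
#'
#' One univariate proportional-hazards fit per listed gene, on z-scored
#' expression.
#'
#' @param X An [expression_matrix()].
#' @param surv A [survival_table()] covering the samples of `X`.
#' @param genes Gene symbols to test.
#' @return Data.frame: gene, hr, ci_low, ci_high, p.
#' @export
forest_table <- function(X, surv, genes = rownames(X)) {
  common <- intersect(colnames(X), surv$sample_id)
  srt <- surv[match(common, surv$sample_id), ]
  genes <- intersect(genes, rownames(X))
  rows <- lapply(genes, function(g) {
    x <- as.numeric(scale(X[g, common]))
    hr <- tryCatch(hazard_ratio(srt$time, srt$event, x), error = function(e) NULL)
    if (is.null(hr)) return(NULL)
    data.frame(gene = g, hr = hr$hr, ci_low = hr$ci_low, ci_high = hr$ci_high,
               p = hr$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Pooled prognostic meta-analysis across cohorts
#'
#' Per cohort: compound scores, per-dataset score normalization, median
#' dichotomization within the cohort, stratification; then a pooled
#' (unstratified) Kaplan-Meier and log-rank over all samples, plus the
#' immu+mese- vs immu+mese+ subgroup contrast.
#'
#' @param cohorts List of lists with elements `expression`
#'   ([expression_matrix()]) and `survival` ([survival_table()]).
#' @param mese_mrs,immu_mrs [gene_set()] objects.
#' @param alpha ssGSEA exponent.
#' @return List: scores (pooled table with survival merged), km (per-group
#'   curves), logrank (3-group test), contrast (immu+mese- vs immu+mese+),
#'   median_by_group.
#' @export
meta_analyze <- function(cohorts, mese_mrs, immu_mrs, alpha = 0.25) {
  if (length(cohorts) < 2L) stop("meta-analysis needs >= 2 cohorts")
  tabs <- lapply(cohorts, function(co) {
    sc <- score_and_stratify(co$expression, mese_mrs, immu_mrs, alpha = alpha)
    merge(sc, as.data.frame(co$survival), by = "sample_id")
  })
  pooled <- do.call(rbind, tabs)
  km <- lapply(split(pooled, pooled$group), function(d)
    if (nrow(d) && sum(d$event) > 0) km_estimate(d$time, d$event) else NULL)
  lr <- logrank_test(pooled$time, pooled$event, pooled$group)
  sub <- pooled[pooled$subgroup %in% c("immu+mese-", "immu+mese+"), ]
  contrast <- if (length(unique(droplevels(sub$subgroup))) == 2L)
    logrank_test(sub$time, sub$event, droplevels(sub$subgroup)) else NULL
  med <- vapply(split(pooled, pooled$group), function(d)
    if (nrow(d) && sum(d$event) > 0) attr(km_estimate(d$time, d$event), "median")
    else NA_real_, numeric(1))
  list(scores = pooled, km = km, logrank = lr, contrast = contrast,
       median_by_group = med)
}

#' Compare score vectors between conditions
#'
#' Paired: Wilcoxon signed-rank on the pair differences (zero differences
#' dropped; all-zero yields p = 1 with a warning). Unpaired: Wilcoxon
#' rank-sum. Two-sided.
#'
#' @param scores_a,scores_b Numeric vectors (equal length when paired).
#' @param paired Logical.
#' @return List: statistic, p, n_effective.
#' @export
compare_scores <- function(scores_a, scores_b, paired = FALSE) {
  if (paired) {
    if (length(scores_a) != length(scores_b))
      stop("paired comparison needs equal lengths")
    d <- scores_a - scores_b
    nz <- d != 0
    if (!any(nz)) {
      warning("all paired differences are zero; p = 1")
      return(list(statistic = NA_real_, p = 1, n_effective = 0L))
    }
    if (sum(nz) < 3L) stop("fewer than 3 non-zero paired differences")
    wt <- suppressWarnings(stats::wilcox.test(scores_a[nz], scores_b[nz],
                                              paired = TRUE, exact = FALSE))
  } else {
    if (length(scores_a) < 3L || length(scores_b) < 3L)
      stop("need at least 3 observations per group")
    wt <- suppressWarnings(stats::wilcox.test(scores_a, scores_b, exact = FALSE))
  }
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_effective = if (paired) sum(scores_a != scores_b) else
         length(scores_a) + length(scores_b))
}

#' Spearman correlation of a compound score with listed genes
#'
#' @param scores Numeric per-sample score vector, aligned to `X` columns.
#' @param X An [expression_matrix()].
#' @param gene_list Genes to correlate.
#' @return Data.frame: gene, rho, p, p_adjusted (BH); constant genes get NA.
#' @export
correlate_score_genes <- function(scores, X, gene_list) {
  gene_list <- intersect(gene_list, rownames(X))
  if (!length(gene_list)) stop("no listed gene present in X")
  rows <- lapply(gene_list, function(g) {
    x <- X[g, ]
    if (length(unique(x)) == 1L)
      return(data.frame(gene = g, rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(scores, x, method = "spearman",
                                           exact = FALSE))
    data.frame(gene = g, rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Load the packaged 16-gene master-regulator signature
#'
#' The two stroma-associated MR lists shipped with the package (6
#' mesenchymal, 10 immunoreactive transcription factors).
#'
#' @return Named list of two [gene_set()]s: `mesenchymal_mrs`,
#'   `immunoreactive_mrs`.
#' @export
mr_signature <- function() {
  path <- system.file("extdata", "mr_signature.gmt", package = "stromaMR")
  if (!nzchar(path)) stop("packaged mr_signature.gmt not found")
  read_gmt(path)
}
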