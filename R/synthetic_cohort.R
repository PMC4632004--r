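# Synthetic bulk-expression cohorts with planted ground truth: four latent
# subtypes, TF regulons with known correlation structure, per-sample stromal
# admixture carrying mesenchymal/immunoreactive signature genes, paired
# designs, and right-censored survival whose hazard depends on the planted
# signature scores.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study conditions every downstream stage is
#' validated against: a 500-gene, 200-sample cohort with four subtypes
#' (Differentiated, Proliferative, Mesenchymal, Immunoreactive), 24 TFs of
#' which 6 are planted mesenchymal and 10 immunoreactive master regulators
#' (18 targets each, target-TF correlation 0.8), stromal fractions higher in
#' the two stroma-associated subtypes, and exponential survival with hazard
#' increasing in the mesenchymal score and decreasing in the immunoreactive
#' score.
#'
#' @param n_genes,n_samples Cohort dimensions.
#' @param n_subtypes Number of latent subtypes (4: the last two are the
#'   stroma-associated mesenchymal and immunoreactive classes).
#' @param n_tfs Total transcription factors (>= n_mese_tfs + n_immu_tfs).
#' @param targets_per_tf Planted targets per TF.
#' @param n_mese_tfs,n_immu_tfs Planted master regulators per stromal program.
#' @param regulon_strength Target Pearson correlation between a TF and its
#'   targets, in (0, 1).
#' @param repressed_fraction Fraction of targets with repressive mode.
#' @param stromal_fraction_range (lo, hi) of admixture fractions; the two
#'   stroma-associated subtypes draw from the upper half.
#' @param noise_sd Gaussian noise SD (log2 units) on non-regulon genes.
#' @param marker_effect Epithelial subtype-marker shift (log2 units).
#' @param stromal_effect Stromal signature shift at f = 1 (log2 units).
#' @param n_markers_per_subtype Epithelial marker genes per marked subtype.
#' @param marker_subtypes How many subtypes (in the order Differentiated,
#'   Proliferative, Mesenchymal, Immunoreactive) carry epithelial marker
#'   blocks. Default 2: the two stroma-associated subtypes are identified by
#'   their stromal programs alone, mirroring their tissue composition.
#' @param survival List: baseline_hazard (events/month), beta_mese (>= 0),
#'   beta_immu (<= 0), censor_rate in [0, 1).
#' @param seed Integer seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_genes = 500L, n_samples = 200L, n_subtypes = 4L,
                          n_tfs = 24L, targets_per_tf = 18L,
                          n_mese_tfs = 6L, n_immu_tfs = 10L,
                          regulon_strength = 0.8, repressed_fraction = 0.25,
                          stromal_fraction_range = c(0.1, 0.6),
                          noise_sd = 0.4, marker_effect = 2,
                          stromal_effect = 3, n_markers_per_subtype = 20L,
                          marker_subtypes = 2L,
                          survival = list(baseline_hazard = 0.02,
                                          beta_mese = log(2),
                                          beta_immu = -log(2),
                                          censor_rate = 0.3),
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_subtypes = as.integer(n_subtypes), n_tfs = as.integer(n_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              n_mese_tfs = as.integer(n_mese_tfs),
              n_immu_tfs = as.integer(n_immu_tfs),
              regulon_strength = regulon_strength,
              repressed_fraction = repressed_fraction,
              stromal_fraction_range = stromal_fraction_range,
              noise_sd = noise_sd, marker_effect = marker_effect,
              stromal_effect = stromal_effect,
              n_markers_per_subtype = as.integer(n_markers_per_subtype),
              marker_subtypes = as.integer(marker_subtypes),
              survival = survival, seed = as.integer(seed))
  with(cfg, {
    if (n_tfs * targets_per_tf > n_genes)
      stop("infeasible config: n_tfs * targets_per_tf exceeds n_genes")
    if (n_mese_tfs + n_immu_tfs > n_tfs)
      stop("infeasible config: planted MR TFs exceed n_tfs")
    if (marker_subtypes < 0 || marker_subtypes > n_subtypes)
      stop("marker_subtypes must be between 0 and n_subtypes")
    if (n_tfs + n_tfs * targets_per_tf + marker_subtypes * n_markers_per_subtype > n_genes)
      stop("infeasible config: TFs + targets + markers exceed n_genes")
    if (regulon_strength <= 0 || regulon_strength >= 1)
      stop("regulon_strength must be in (0, 1)")
    if (repressed_fraction < 0 || repressed_fraction > 1)
      stop("repressed_fraction must be in [0, 1]")
    if (length(stromal_fraction_range) != 2L ||
        diff(stromal_fraction_range) < 0 ||
        any(stromal_fraction_range < 0) || any(stromal_fraction_range > 1))
      stop("stromal_fraction_range must be an ordered pair within [0, 1]")
    if (noise_sd <= 0) stop("noise_sd must be positive")
    if (survival$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
    if (survival$beta_mese < 0) stop("beta_mese must be >= 0")
    if (survival$beta_immu > 0) stop("beta_immu must be <= 0")
    if (survival$censor_rate < 0 || survival$censor_rate >= 1)
      stop("censor_rate must be in [0, 1)")
  })
  structure(cfg, class = "cohort_config")
}

subtype_names <- c("Differentiated", "Proliferative", "Mesenchymal", "Immunoreactive")

#' Generate a synthetic cohort with planted ground truth
#'
#' Construction, in order: (1) subtype labels drawn uniformly; (2) epithelial
#' profiles from subtype-specific marker genes, scaled by 1 - f; (3) TF
#' expression i.i.d. standard normal with each target =
#' mode * a * TF + sqrt(1 - a^2) * noise, a = `regulon_strength`;
#' (4) a stromal profile over-expressing the planted mesenchymal and
#' immunoreactive signatures (each = its MR TFs plus their targets), with
#' subtype-dependent weights (the matching stromal subtype emphasises its own
#' program); (5) observed sample = epithelial + f * stromal with f drawn from
#' the upper half of the range for the two stroma-associated subtypes;
#' (6) exponential survival with hazard
#' lambda * exp(beta_mese * z_mese + beta_immu * z_immu), z the standardized
#' per-sample signature means, and independent exponential censoring
#' calibrated to the configured censor rate.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: expression ([expression_matrix()]),
#'   true_subtype, true_regulons (tf -> targets, mode), stromal_fraction,
#'   mese_signature / immu_signature ([gene_set()]), tf_list, survival
#'   ([survival_table()]), truth_betas, config.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  rng <- local_rng(cfg$seed)
  ns <- cfg$n_samples
  sample_ids <- sprintf("S%03d", seq_len(ns))

  # gene panel
  tf_class <- c(rep("mese", cfg$n_mese_tfs), rep("immu", cfg$n_immu_tfs),
                rep("background", cfg$n_tfs - cfg$n_mese_tfs - cfg$n_immu_tfs))
  tf_ids <- sprintf("TF%s%02d", c("M", "I", "B")[match(tf_class, c("mese", "immu", "background"))],
                    c(seq_len(cfg$n_mese_tfs), seq_len(cfg$n_immu_tfs),
                      seq_len(cfg$n_tfs - cfg$n_mese_tfs - cfg$n_immu_tfs)))
  target_ids <- unlist(lapply(seq_len(cfg$n_tfs), function(k)
    sprintf("%s_T%02d", tf_ids[k], seq_len(cfg$targets_per_tf))))
  marker_sets <- lapply(seq_len(cfg$marker_subtypes), function(s)
    sprintf("M%s%02d", toupper(substr(subtype_names[s], 1, 3)),
            seq_len(cfg$n_markers_per_subtype)))
  names(marker_sets) <- subtype_names[seq_len(cfg$marker_subtypes)]
  n_filler <- cfg$n_genes - length(tf_ids) - length(target_ids) -
    sum(lengths(marker_sets))
  filler <- if (n_filler > 0) sprintf("G%03d", seq_len(n_filler)) else character(0)
  genes <- c(tf_ids, target_ids, unlist(marker_sets, use.names = FALSE), filler)

  # (1) subtype labels, uniform
  subtype <- subtype_names[rng$sample_int(cfg$n_subtypes, ns, replace = TRUE)]
  names(subtype) <- sample_ids

  # (5-prep) stromal fractions: stroma-associated subtypes draw high
  lo <- cfg$stromal_fraction_range[1]; hi <- cfg$stromal_fraction_range[2]
  mid <- (lo + hi) / 2
  stromal <- subtype %in% c("Mesenchymal", "Immunoreactive")
  f <- numeric(ns)
  f[stromal] <- rng$runif(sum(stromal), mid, hi)
  f[!stromal] <- rng$runif(sum(!stromal), lo, mid)
  names(f) <- sample_ids

  # per-sample stromal program weights
  w_mese <- ifelse(subtype == "Mesenchymal", 1, 0.5)
  w_immu <- ifelse(subtype == "Immunoreactive", 1, 0.5)

  # (3) regulon latent structure
  a <- cfg$regulon_strength
  tf_latent <- matrix(rng$rnorm(cfg$n_tfs * ns), cfg$n_tfs, ns,
                      dimnames = list(tf_ids, sample_ids))
  modes <- lapply(seq_len(cfg$n_tfs), function(k) {
    m <- ifelse(rng$runif(cfg$targets_per_tf) < cfg$repressed_fraction, -1L, 1L)
    stats::setNames(m, sprintf("%s_T%02d", tf_ids[k], seq_len(cfg$targets_per_tf)))
  })
  names(modes) <- tf_ids
  R <- matrix(0, length(genes), ns, dimnames = list(genes, sample_ids))
  R[tf_ids, ] <- tf_latent
  for (k in seq_len(cfg$n_tfs)) {
    tg <- names(modes[[k]])
    eps <- matrix(rng$rnorm(length(tg) * ns), length(tg), ns)
    R[tg, ] <- modes[[k]] * a * matrix(tf_latent[k, ], length(tg), ns, byrow = TRUE) +
      sqrt(1 - a^2) * eps
  }

  # (4) stromal program membership: MR TFs plus their targets
  mese_genes <- c(tf_ids[tf_class == "mese"],
                  unlist(lapply(which(tf_class == "mese"), function(k) names(modes[[k]]))))
  immu_genes <- c(tf_ids[tf_class == "immu"],
                  unlist(lapply(which(tf_class == "immu"), function(k) names(modes[[k]]))))
  sm <- as.numeric(genes %in% mese_genes); names(sm) <- genes
  si <- as.numeric(genes %in% immu_genes); names(si) <- genes

  # (2) epithelial marker structure (one metagene block per subtype),
  # scaled by 1 - f at assembly
  M <- matrix(0, length(genes), ns, dimnames = list(genes, sample_ids))
  for (s in names(marker_sets))
    M[marker_sets[[s]], subtype == s] <- cfg$marker_effect

  # base noise on non-regulon genes
  non_reg <- setdiff(genes, c(tf_ids, target_ids))
  B0 <- matrix(0, length(genes), ns, dimnames = list(genes, sample_ids))
  B0[non_reg, ] <- cfg$noise_sd * rng$rnorm(length(non_reg) * ns)

  E <- assemble_expression(B0, M, R, sm, si, f, w_mese, w_immu, cfg$stromal_effect)
  X <- expression_matrix(E, dataset_id = "synthetic")

  # (6) survival truth from the observed signature means
  z_mese <- scale(colMeans(E[mese_genes, , drop = FALSE]))[, 1]
  z_immu <- scale(colMeans(E[immu_genes, , drop = FALSE]))[, 1]
  sv <- cfg$survival
  hazard <- sv$baseline_hazard * exp(sv$beta_mese * z_mese + sv$beta_immu * z_immu)
  t_event <- rng$rexp(ns, 1) / hazard
  if (sv$censor_rate > 0) {
    # independent exponential censoring; its rate solves
    # mean_j[ lc / (lc + h_j) ] = censor_rate
    censor_rate_param <- stats::uniroot(
      function(lc) mean(lc / (lc + hazard)) - sv$censor_rate,
      lower = min(hazard) * 1e-6, upper = max(hazard) * 1e6, tol = 1e-10)$root
    t_cens <- rng$rexp(ns, censor_rate_param)
  } else t_cens <- rep(Inf, ns)
  time <- pmin(t_event, t_cens)
  event <- as.numeric(t_event <= t_cens)
  surv <- survival_table(sample_ids, time, event, cohort_id = "synthetic")

  regulons <- lapply(seq_len(cfg$n_tfs), function(k)
    list(tf = tf_ids[k], targets = names(modes[[k]]), mode = modes[[k]],
         class = tf_class[k]))
  names(regulons) <- tf_ids

  structure(list(
    expression = X,
    true_subtype = subtype,
    true_regulons = regulons,
    stromal_fraction = f,
    mese_signature = gene_set("mese_signature", mese_genes,
                              "planted mesenchymal stromal program"),
    immu_signature = gene_set("immu_signature", immu_genes,
                              "planted immunoreactive stromal program"),
    mese_mrs = gene_set("mese_mrs", tf_ids[tf_class == "mese"],
                        "planted mesenchymal master regulators"),
    immu_mrs = gene_set("immu_mrs", tf_ids[tf_class == "immu"],
                        "planted immunoreactive master regulators"),
    tf_list = tf_ids,
    survival = surv,
    truth_betas = c(beta_mese = sv$beta_mese, beta_immu = sv$beta_immu),
    config = cfg,
    internals = list(M = M, R = R, sm = sm, si = si,
                     w_mese = w_mese, w_immu = w_immu, non_reg = non_reg)
  ), class = "synthetic_cohort")
}

assemble_expression <- function(B0, M, R, sm, si, f, w_mese, w_immu, stromal_effect) {
  epithelial <- sweep(M, 2L, 1 - f, `*`)
  stromal <- stromal_effect * (outer(sm, f * w_mese) + outer(si, f * w_immu))
  B0 + epithelial + R + stromal
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genes x %d samples, %d TFs (%d+%d planted MRs)\n",
              nrow(x$expression), ncol(x$expression), x$config$n_tfs,
              x$config$n_mese_tfs, x$config$n_immu_tfs))
  invisible(x)
}

#' Generate a paired design from a synthetic cohort
#'
#' Rebuilds selected samples at counterfactual stromal fractions while
#' keeping their latent tumor state (regulon activity, subtype markers):
#' \describe{
#'   \item{stroma_vs_epithelium}{pure stroma (f = 1) vs pure epithelium
#'     (f = 0) members per pair.}
#'   \item{primary_vs_pdx}{the sample at its native f vs the same sample
#'     with f forced to ~0 (host stroma replaces human stroma).}
#'   \item{primary_vs_metastasis, treated_vs_untreated}{native f vs f
#'     shifted up by `delta` (stromal involvement increases with
#'     progression or treatment).}
#' }
#' Fresh measurement noise is drawn for every emitted member.
#'
#' @param cohort A `synthetic_cohort`.
#' @param design One of the four design names.
#' @param n_pairs Number of pairs (>= 2); default 9.
#' @param seed Integer seed.
#' @param delta Upward f shift for the metastasis / treated designs.
#' @return List: expression ([expression_matrix()], 2 * n_pairs columns) and
#'   `pairs`, a data.frame (pair, sample_id, member_a, member_b, f_a, f_b)
#'   where member_a is the baseline condition.
#' @export
generate_paired_design <- function(cohort,
                                   design = c("stroma_vs_epithelium", "primary_vs_pdx",
                                              "primary_vs_metastasis", "treated_vs_untreated"),
                                   n_pairs = 9L, seed = 1L, delta = 0.15) {
  design <- match.arg(design)
  if (n_pairs < 2L) stop("n_pairs must be >= 2")
  if (n_pairs > ncol(cohort$expression))
    stop("n_pairs exceeds cohort size")
  rng <- local_rng(seed)
  picked <- sort(rng$sample_int(ncol(cohort$expression), n_pairs))
  ids <- colnames(cohort$expression)[picked]
  f0 <- cohort$stromal_fraction[ids]
  fa_fb <- switch(design,
    stroma_vs_epithelium = list(a = rep(1, n_pairs), b = rep(0, n_pairs),
                                lab = c("stroma", "epithelium")),
    primary_vs_pdx = list(a = f0, b = rep(0.02, n_pairs),
                          lab = c("primary", "pdx")),
    primary_vs_metastasis = list(a = f0, b = pmin(f0 + delta, 1),
                                 lab = c("primary", "metastasis")),
    treated_vs_untreated = list(a = f0, b = pmin(f0 + delta, 1),
                                lab = c("untreated", "treated")))
  int <- cohort$internals
  cfg <- cohort$config
  build <- function(j_global, f_new, b0) {
    (1 - f_new) * int$M[, j_global] + int$R[, j_global] + b0 +
      cfg$stromal_effect * (int$sm * f_new * int$w_mese[j_global] +
                            int$si * f_new * int$w_immu[j_global])
  }
  # one fresh base-noise draw per pair: both members describe the same
  # latent tumor, so they share everything except the admixture terms
  pair_noise <- lapply(seq_len(n_pairs), function(i) {
    b0 <- numeric(nrow(cohort$expression))
    names(b0) <- rownames(cohort$expression)
    b0[int$non_reg] <- cfg$noise_sd * rng$rnorm(length(int$non_reg))
    b0
  })
  cols_a <- sapply(seq_len(n_pairs), function(i)
    build(picked[i], fa_fb$a[i], pair_noise[[i]]))
  cols_b <- sapply(seq_len(n_pairs), function(i)
    build(picked[i], fa_fb$b[i], pair_noise[[i]]))
  member_a <- sprintf("%s_%s", ids, fa_fb$lab[1])
  member_b <- sprintf("%s_%s", ids, fa_fb$lab[2])
  E <- cbind(cols_a, cols_b)
  colnames(E) <- c(member_a, member_b)
  rownames(E) <- rownames(cohort$expression)
  list(expression = expression_matrix(E, dataset_id = design),
       pairs = data.frame(pair = seq_len(n_pairs), sample_id = ids,
                          member_a = member_a, member_b = member_b,
                          f_a = unname(fa_fb$a), f_b = unname(fa_fb$b),
                          stringsAsFactors = FALSE))
}
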