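# Consensus molecular subtyping and signature derivation: NMF with
# multiplicative updates, consensus clustering over column subsamples,
# silhouette core-sample filtering, multiclass SAM gene selection, and a
# nearest-shrunken-centroid (PAM) classifier.

#' Non-negative matrix factorization of an expression matrix
#'
#' Each gene row is shifted by its minimum to enforce non-negativity (the
#' within-gene ordering is preserved), then V ~ W H is fitted by Lee-Seung
#' multiplicative updates under the Frobenius objective. Iterations stop
#' when the relative objective change drops below `tol` or after `max_iter`
#' iterations; the best of `n_restarts` random initializations (by final
#' objective) is returned. Sample labels are the argmax metagene of H.
#'
#' @param X An [expression_matrix()] (or plain matrix with dimnames).
#' @param k Number of metagenes (>= 2).
#' @param n_restarts Random restarts.
#' @param seed Integer seed.
#' @param max_iter,tol Stopping rule.
#' @return List: W (genes x k), H (k x samples), labels (named integer),
#'   objective, objective_trace (of the winning restart).
#' @export
nmf_factorize <- function(X, k, n_restarts = 5, seed = 1L,
                          max_iter = 500L, tol = 1e-6) {
  if (k < 2L) stop("k must be >= 2")
  if (k > min(dim(X))) stop("k exceeds matrix dimensions")
  V <- X - apply(X, 1L, min)           # per-gene shift to non-negative
  if (any(rowSums(V) == 0))
    stop("all-zero row after non-negativity shift (constant gene); ",
         "filter constant genes before factorization")
  rng <- local_rng(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W <- matrix(rng$runif(nrow(V) * k, 0.1, 1), nrow(V), k)
    H <- matrix(rng$runif(k * ncol(V), 0.1, 1), k, ncol(V))
    obj <- sum((V - W %*% H)^2)
    trace <- obj
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V) / pmax(crossprod(W, W %*% H), 1e-12))
      W <- W * (V %*% t(H) / pmax(W %*% tcrossprod(H), 1e-12))
      new_obj <- sum((V - W %*% H)^2)
      if (new_obj > obj * (1 + 1e-9))
        stop("NMF objective increased; numerical failure")
      trace <- c(trace, new_obj)
      if ((obj - new_obj) <= tol * obj) { obj <- new_obj; break }
      obj <- new_obj
    }
    if (is.null(best) || obj < best$objective)
      best <- list(W = W, H = H, objective = obj, objective_trace = trace)
  }
  # fix the W/H scale ambiguity before reading labels off H:
  # normalize W columns to unit sum, compensate in H
  csum <- pmax(colSums(best$W), 1e-12)
  best$W <- sweep(best$W, 2L, csum, `/`)
  best$H <- best$H * csum
  labels <- apply(best$H, 2L, which.max)
  names(labels) <- colnames(X)
  dimnames(best$W) <- list(rownames(X), paste0("metagene", seq_len(k)))
  dimnames(best$H) <- list(paste0("metagene", seq_len(k)), colnames(X))
  c(best, list(labels = labels))
}

# k-means++ seeding followed by Lloyd iterations via stats::kmeans;
# `n_start` independent seedings, best total within-SS kept.
kmeans_pp <- function(data, k, rng, n_start = 10L) {
  n <- nrow(data)
  best <- NULL
  for (s in seq_len(n_start)) {
    centers <- matrix(NA_real_, k, ncol(data))
    centers[1L, ] <- data[rng$sample_int(n, 1L), ]
    d2 <- rowSums((data - matrix(centers[1L, ], n, ncol(data), byrow = TRUE))^2)
    for (c_i in seq_len(k)[-1L]) {
      prob <- d2 / sum(d2)
      pick <- findInterval(rng$runif(1L), cumsum(prob)) + 1L
      pick <- min(pick, n)
      centers[c_i, ] <- data[pick, ]
      d2 <- pmin(d2, rowSums((data - matrix(centers[c_i, ], n, ncol(data),
                                            byrow = TRUE))^2))
    }
    fit <- suppressWarnings(stats::kmeans(data, centers = centers, iter.max = 50L))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best$cluster
}

#' Consensus clustering over column subsamples
#'
#' For each k in `k_range` the samples are repeatedly subsampled
#' (`subsample_fraction` of columns), clustered with the chosen method, and
#' the consensus matrix entry (i, j) is the fraction of co-subsampled
#' replicates in which i and j landed in the same cluster. Final labels come
#' from average-linkage hierarchical clustering of 1 - consensus; the
#' cophenetic correlation of that tree against 1 - consensus is reported for
#' rank selection.
#'
#' @param X An [expression_matrix()].
#' @param k_range Integer vector of cluster counts to evaluate.
#' @param method `"kmeans"` (k-means++ on sample profiles) or `"nmf"`.
#' @param n_reps Subsampling replicates (>= 2).
#' @param subsample_fraction Fraction of samples per replicate, in (0, 1].
#' @param seed Integer seed.
#' @param nmf_restarts Restarts per replicate when `method = "nmf"`.
#' @return Named list (one per k) of `consensus_result`: k, consensus_matrix,
#'   labels, cophenetic, method.
#' @export
consensus_cluster <- function(X, k_range, method = c("kmeans", "nmf"),
                              n_reps = 50L, subsample_fraction = 0.8,
                              seed = 1L, nmf_restarts = 1L) {
  method <- match.arg(method)
  if (n_reps < 2L) stop("n_reps must be >= 2")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  n <- ncol(X)
  ids <- colnames(X)
  rng <- local_rng(seed)
  out <- lapply(k_range, function(k) {
    co <- matrix(0, n, n)
    tog <- matrix(0, n, n)
    for (b in seq_len(n_reps)) {
      m <- max(k + 1L, round(subsample_fraction * n))
      idx <- sort(rng$sample_int(n, min(m, n)))
      cl <- if (method == "kmeans") {
        kmeans_pp(t(X[, idx, drop = FALSE]), k, rng)
      } else {
        sub_seed <- rng$sample_int(.Machine$integer.max, 1L)
        nmf_factorize(X[, idx, drop = FALSE], k, n_restarts = nmf_restarts,
                      seed = sub_seed)$labels
      }
      same <- outer(cl, cl, "==") * 1
      co[idx, idx] <- co[idx, idx] + same
      tog[idx, idx] <- tog[idx, idx] + 1
    }
    off <- tog[upper.tri(tog)]
    if (any(off == 0))
      stop("some sample pairs were never co-subsampled; increase n_reps")
    consensus <- co / tog
    diag(consensus) <- 1
    dimnames(consensus) <- list(ids, ids)
    d <- stats::as.dist(1 - consensus)
    hc <- stats::hclust(d, method = "average")
    labels <- stats::cutree(hc, k = k)
    coph <- stats::cor(stats::cophenetic(hc), d)
    structure(list(k = k, consensus_matrix = consensus, labels = labels,
                   cophenetic = coph, method = method),
              class = "consensus_result")
  })
  names(out) <- paste0("k", k_range)
  out
}

#' Silhouette widths and core-sample filtering
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a(i) the mean dissimilarity
#' to the sample's own cluster and b(i) the smallest mean dissimilarity to
#' any other cluster. Samples with positive width form the core set.
#' Members of singleton clusters get width 0 and are flagged.
#'
#' @param dissimilarity Symmetric sample-by-sample matrix, zero diagonal.
#' @param labels Cluster labels (named by sample or aligned to the matrix).
#' @return List: widths (named numeric), core_samples (names with s > 0),
#'   flagged_singletons.
#' @export
silhouette_filter <- function(dissimilarity, labels) {
  D <- as.matrix(dissimilarity)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("dissimilarity must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("dissimilarity must have zero diagonal")
  n <- nrow(D)
  labels <- as.vector(labels)
  if (length(labels) != n) stop("labels must match the matrix dimension")
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  ids <- rownames(D) %||% as.character(seq_len(n))
  widths <- numeric(n)
  singleton <- logical(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { widths[i] <- 0; singleton[i] <- TRUE; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(D[i, labels == g]), numeric(1)))
    widths[i] <- (b - a) / max(a, b)
  }
  names(widths) <- ids
  list(widths = widths, core_samples = ids[widths > 0],
       flagged_singletons = ids[singleton])
}

#' Multiclass SAM statistic with permutation q-values
#'
#' Per gene, d is a standardized between-class contrast: the root
#' mean-square class-mean deviation (weighted by class size, on K - 1
#' degrees of freedom) over (s_i + s0), where s_i is the pooled within-class
#' standard deviation and the exchangeability factor s0 is the median of the
#' s_i. Q-values are estimated from label permutations: for each gene's
#' threshold |d|, the expected false count is the median permutation count
#' of |d*| at or above the threshold, divided by the observed count, clamped
#' to [0, 1] and made monotone.
#'
#' @param X An [expression_matrix()].
#' @param labels Class labels per sample (>= 2 classes of >= 2 samples).
#' @param n_permutations Label permutations.
#' @param seed Integer seed.
#' @return Data.frame: gene, d, q.
#' @export
sam_multiclass <- function(X, labels, n_permutations = 200L, seed = 1L) {
  labels <- as.vector(labels)
  if (length(labels) != ncol(X)) stop("labels must match samples")
  tab <- table(labels)
  if (length(tab) < 2L) stop("need >= 2 classes")
  if (any(tab < 2L)) stop("every class needs >= 2 samples")
  d_stat <- function(lab) {
    lab <- as.character(lab)
    classes <- unique(lab)
    Kc <- length(classes)
    n <- length(lab)
    overall <- rowMeans(X)
    between <- 0
    ss_within <- 0
    for (g in classes) {
      idx <- lab == g
      mk <- rowMeans(X[, idx, drop = FALSE])
      between <- between + sum(idx) * (mk - overall)^2
      ss_within <- ss_within + rowSums((X[, idx, drop = FALSE] - mk)^2)
    }
    s <- sqrt(ss_within / (n - Kc))
    list(d = sqrt(between / (Kc - 1)) / (s + stats::median(s)), s = s)
  }
  obs <- d_stat(labels)$d
  rng <- local_rng(seed)
  G <- nrow(X)
  thresholds <- sort(abs(obs))
  null_counts <- matrix(0, n_permutations, G)
  for (b in seq_len(n_permutations)) {
    perm <- labels[rng$sample_int(length(labels))]
    dp <- sort(abs(d_stat(perm)$d))
    # count of |d*| >= each observed threshold
    null_counts[b, ] <- G - findInterval(thresholds - 1e-12, dp)
  }
  med_null <- apply(null_counts, 2L, stats::median)
  obs_counts <- G - findInterval(thresholds - 1e-12, sort(abs(obs)))
  fdr_raw <- pmin(pmax(med_null / pmax(obs_counts, 1L), 0), 1)
  # q(gene) = min raw FDR over this and all less stringent thresholds
  # (Storey-style step-up; thresholds are in ascending |d| order)
  q_at_threshold <- cummin(fdr_raw)
  q <- q_at_threshold[match(abs(obs), thresholds)]
  data.frame(gene = rownames(X), d = obs, q = q,
             row.names = NULL, stringsAsFactors = FALSE)
}

soft_threshold <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

pam_fit_centroids <- function(X, labels) {
  classes <- sort(unique(labels))
  n <- ncol(X)
  Kc <- length(classes)
  overall <- rowMeans(X)
  centroids <- sapply(classes, function(g)
    rowMeans(X[, labels == g, drop = FALSE]))
  colnames(centroids) <- as.character(classes)
  rownames(centroids) <- rownames(X)
  nk <- vapply(classes, function(g) sum(labels == g), numeric(1))
  ss <- 0
  for (g in classes) ss <- ss +
      rowSums((X[, labels == g, drop = FALSE] - centroids[, as.character(g)])^2)
  s <- sqrt(ss / (n - Kc))
  s0 <- stats::median(s)
  mk <- sqrt(1 / nk - 1 / n)
  dik <- (centroids - overall) / outer(s + s0, mk)
  list(classes = classes, overall = overall, centroids = centroids,
       s = s, s0 = s0, mk = mk, dik = dik)
}

pam_shrunken <- function(fit, delta) {
  dshr <- soft_threshold(fit$dik, delta)
  shrunk <- fit$overall + dshr * outer(fit$s + fit$s0, fit$mk)
  list(dshr = dshr, centroids = shrunk)
}

pam_classify <- function(fit, dshr_centroids, newX) {
  genes <- intersect(rownames(newX), names(fit$overall))
  sc <- (fit$s + fit$s0)[genes]
  cen <- dshr_centroids$centroids[genes, , drop = FALSE]
  disc <- sapply(seq_along(fit$classes), function(ci) {
    colSums(((newX[genes, , drop = FALSE] - cen[, ci])/sc)^2)
  })
  cls <- fit$classes[max.col(-disc, ties.method = "first")]
  stats::setNames(cls, colnames(newX))
}

#' Train a nearest-shrunken-centroid (PAM) subtype classifier
#'
#' Standardized centroid contrasts d_ik = (xbar_ik - xbar_i) /
#' (m_k (s_i + s0)) are soft-thresholded by delta; the shrinkage level is
#' chosen by stratified cross-validation (lowest error, ties broken toward
#' the largest delta, i.e. the most parsimonious signature). Genes with any
#' surviving nonzero shrunken component form the signature; each signature
#' gene is assigned to the class of its largest positive component, giving
#' per-subtype up-regulated lists. Class priors are uniform.
#'
#' @param X An [expression_matrix()] restricted to SAM-selected genes.
#' @param labels Class labels per sample.
#' @param delta_grid Shrinkage grid; default 30 points from 0 to max |d_ik|.
#' @param cv_folds Stratified folds.
#' @param seed Integer seed for fold assignment.
#' @return A `subtype_signature`: fit pieces, chosen delta, cv_error_curve,
#'   resubstitution error, signature genes, per-subtype up gene sets.
#' @export
pam_train <- function(X, labels, delta_grid = NULL, cv_folds = 5L, seed = 1L) {
  labels <- as.vector(labels)
  fit <- pam_fit_centroids(X, labels)
  if (is.null(delta_grid))
    delta_grid <- seq(0, max(abs(fit$dik)), length.out = 30L)
  rng <- local_rng(seed)
  # stratified folds
  folds <- integer(length(labels))
  for (g in fit$classes) {
    idx <- which(labels == g)
    if (length(idx) < cv_folds && length(idx) < 2L)
      stop("class '", g, "' too small for cross-validation")
    folds[idx] <- (rng$sample_int(length(idx)) %% cv_folds) + 1L
  }
  cv_err <- numeric(length(delta_grid))
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < length(fit$classes))
      stop("fold ", f, " lost a class; reduce cv_folds")
    fit_f <- pam_fit_centroids(X[, tr, drop = FALSE], labels[tr])
    for (di in seq_along(delta_grid)) {
      shr <- pam_shrunken(fit_f, delta_grid[di])
      pred <- pam_classify(fit_f, shr, X[, !tr, drop = FALSE])
      cv_err[di] <- cv_err[di] + sum(pred != labels[!tr])
    }
  }
  cv_err <- cv_err / length(labels)
  best <- max(which(cv_err == min(cv_err)))       # tie -> largest delta
  delta <- delta_grid[best]
  shr <- pam_shrunken(fit, delta)
  sig_genes <- rownames(X)[rowSums(abs(shr$dshr) > 0) > 0]
  if (!length(sig_genes))
    stop("chosen shrinkage removed every gene; signature is empty")
  resub <- mean(pam_classify(fit, shr, X) != labels)
  up_sets <- lapply(seq_along(fit$classes), function(ci) {
    g <- sig_genes[shr$dshr[sig_genes, ci] > 0 &
                     apply(shr$dshr[sig_genes, , drop = FALSE], 1L, which.max) == ci]
    if (length(g)) gene_set(paste0("subtype_", fit$classes[ci], "_up"), g)
  })
  names(up_sets) <- as.character(fit$classes)
  structure(list(fit = fit, delta = delta, dshr = shr$dshr,
                 shrunken_centroids = shr$centroids,
                 cv_error_curve = data.frame(delta = delta_grid, cv_error = cv_err),
                 resubstitution_error = resub,
                 signature_genes = sig_genes,
                 up_sets = up_sets[!vapply(up_sets, is.null, logical(1))],
                 classes = fit$classes),
            class = "subtype_signature")
}

#' Predict subtype labels with a trained PAM classifier
#'
#' @param signature A `subtype_signature` from [pam_train()].
#' @param X Expression matrix; at least `min_overlap` of the signature genes
#'   must be present.
#' @param min_overlap Minimum fraction of signature genes required.
#' @return Named vector of class labels.
#' @export
pam_predict <- function(signature, X, min_overlap = 0.8) {
  present <- intersect(signature$signature_genes, rownames(X))
  frac <- length(present) / length(signature$signature_genes)
  if (frac < min_overlap) {
    missing <- setdiff(signature$signature_genes, rownames(X))
    stop(sprintf("only %.0f%% of signature genes present (need %.0f%%); missing: %s",
                 100 * frac, 100 * min_overlap,
                 paste(utils::head(missing, 10L), collapse = ", ")))
  }
  pam_classify(signature$fit,
               list(centroids = signature$shrunken_centroids), X)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples;
#' 1 means identical partitions (up to label names), 0 the chance level.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
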