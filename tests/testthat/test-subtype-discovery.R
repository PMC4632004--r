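test_that("NMF recovers a separable block structure exactly and deterministically", {
  set.seed(1)
  V <- rbind(cbind(matrix(runif(50, 1, 2), 5, 10), matrix(0.01, 5, 10)),
             cbind(matrix(0.01, 5, 10), matrix(runif(50, 1, 2), 5, 10)))
  dimnames(V) <- list(paste0("g", 1:10), paste0("s", 1:20))
  f1 <- nmf_factorize(V, 2, n_restarts = 3, seed = 7)
  expect_equal(adjusted_rand_index(f1$labels, rep(1:2, each = 10)), 1)
  f2 <- nmf_factorize(V, 2, n_restarts = 3, seed = 7)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  # objective is monotone non-increasing across iterations
  expect_true(all(diff(f1$objective_trace) <= 1e-9 * f1$objective_trace[-length(f1$objective_trace)]))
  expect_true(all(f1$W >= 0) && all(f1$H >= 0))
})

test_that("NMF rejects invalid inputs", {
  x <- toy_expression(6, 5)
  expect_error(nmf_factorize(x, 10), "exceeds")
  flat <- unclass(x); flat[1, ] <- 2
  expect_error(nmf_factorize(expression_matrix(flat), 2), "constant")
})

test_that("NMF labels recover planted subtypes on a subtype-dominated cohort", {
  co <- generate_cohort(cohort_config(
    n_genes = 300, n_samples = 120, n_tfs = 4, targets_per_tf = 10,
    n_mese_tfs = 2, n_immu_tfs = 2, n_markers_per_subtype = 40,
    marker_subtypes = 4, marker_effect = 3, noise_sd = 0.1, seed = 2))
  f <- nmf_factorize(co$expression, 4, n_restarts = 10, seed = 3)
  expect_gte(adjusted_rand_index(f$labels, co$true_subtype), 0.9)
})

test_that("consensus matrices are valid and near-binary for separated clusters", {
  set.seed(3)
  X <- cbind(matrix(rnorm(40 * 12, 0), 40, 12), matrix(rnorm(40 * 12, 6), 40, 12))
  dimnames(X) <- list(paste0("g", 1:40), paste0("s", 1:24))
  cc <- consensus_cluster(expression_matrix(X), 2, method = "kmeans",
                          n_reps = 20, seed = 5)[[1]]
  M <- cc$consensus_matrix
  expect_true(isSymmetric(M))
  expect_true(all(M >= 0 & M <= 1))
  expect_true(all(diag(M) == 1))
  expect_true(all(M[M > 0.5] > 0.99) && all(M[M < 0.5] < 0.01))
  expect_gt(cc$cophenetic, 0.99)
  expect_equal(adjusted_rand_index(cc$labels, rep(1:2, each = 12)), 1)
})

test_that("full subsampling with deterministic clustering gives a binary consensus", {
  set.seed(4)
  X <- cbind(matrix(rnorm(30 * 10, 0), 30, 10), matrix(rnorm(30 * 10, 8), 30, 10))
  dimnames(X) <- list(paste0("g", 1:30), paste0("s", 1:20))
  cc <- consensus_cluster(expression_matrix(X), 2, method = "kmeans",
                          n_reps = 10, subsample_fraction = 1, seed = 5)[[1]]
  expect_true(all(cc$consensus_matrix %in% c(0, 1)))
})

test_that("rank selection prefers the planted k on the default cohort", {
  co <- generate_cohort(cohort_config())
  cc <- consensus_cluster(co$expression, c(4, 5), method = "kmeans",
                          n_reps = 25, seed = 7)
  expect_gt(cc$k4$cophenetic, cc$k5$cophenetic)
})

test_that("silhouette widths match the cluster-package oracle and filter misfits", {
  set.seed(6)
  pts <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2), matrix(rnorm(20, 5, 0.2), 10, 2))
  D <- as.matrix(dist(pts))
  labels <- rep(1:2, each = 10)
  res <- silhouette_filter(D, labels)
  oracle <- cluster::silhouette(labels, dmatrix = D)[, "sil_width"]
  expect_equal(unname(res$widths), unname(oracle), tolerance = 1e-12)
  expect_true(all(res$widths > 0.9))
  expect_identical(res$core_samples, rownames(D) %||% as.character(1:20))

  # a deliberately mislabeled point gets negative width and is filtered
  wrong <- labels; wrong[1] <- 2
  res2 <- silhouette_filter(D, wrong)
  expect_lt(res2$widths[1], 0)
  expect_false("1" %in% res2$core_samples)

  # singleton clusters are flagged with width 0
  res3 <- silhouette_filter(D, c(3, labels[-1]))
  expect_equal(unname(res3$widths[1]), 0)
  expect_identical(res3$flagged_singletons, "1")
})

test_that("silhouette filtering trims boundary samples at a plausible rate", {
  set.seed(7)
  n_core <- 45; n_bound <- 10
  pts <- rbind(matrix(rnorm(2 * n_core, 0, 0.5), n_core, 2),
               matrix(rnorm(2 * n_core, 4, 0.5), n_core, 2),
               cbind(rnorm(n_bound, 2, 0.3), rnorm(n_bound, 2, 0.3)))
  D <- as.matrix(dist(pts))
  labels <- c(rep(1, n_core), rep(2, n_core), rep(1:2, length.out = n_bound))
  res <- silhouette_filter(D, labels)
  frac <- 1 - length(res$core_samples) / nrow(D)
  expect_gte(frac, 0.05)
  expect_lte(frac, 0.20)
})

test_that("SAM: constant genes score zero with q = 1; null is calibrated", {
  co <- generate_cohort(small_cohort_config(seed = 4))
  X <- unclass(co$expression)
  X["G001", ] <- 5  # constant gene
  labels <- co$true_subtype
  res <- sam_multiclass(expression_matrix(X), labels, n_permutations = 50, seed = 1)
  row <- res[res$gene == "G001", ]
  expect_equal(row$d, 0)
  expect_equal(row$q, 1)
  expect_true(all(res$q >= 0 & res$q <= 1))
  # q monotone: larger |d| never has larger q
  o <- order(abs(res$d), decreasing = TRUE)
  expect_true(all(diff(res$q[o]) >= -1e-12))

  # under permuted labels the observed statistics match their own null
  set.seed(2)
  perm_labels <- sample(labels)
  null_res <- sam_multiclass(co$expression, perm_labels,
                             n_permutations = 50, seed = 3)
  ref <- sam_multiclass(co$expression, sample(perm_labels),
                        n_permutations = 50, seed = 4)
  expect_gt(suppressWarnings(ks.test(null_res$d, ref$d))$p.value, 0.01)
})

test_that("SAM recovers planted multiclass markers with controlled FDR", {
  set.seed(9)
  n <- 80; g <- 400; n_markers <- 40
  labels <- rep(1:4, each = n / 4)
  X <- matrix(rnorm(g * n), g, n,
              dimnames = list(sprintf("g%03d", 1:g), sprintf("s%03d", 1:n)))
  marker_class <- rep(1:4, length.out = n_markers)
  for (i in seq_len(n_markers))
    X[i, labels == marker_class[i]] <- X[i, labels == marker_class[i]] + 2
  res <- sam_multiclass(expression_matrix(X), labels,
                        n_permutations = 100, seed = 5)
  called <- res$gene[res$q < 0.05]
  truth <- rownames(X)[seq_len(n_markers)]
  expect_gte(mean(truth %in% called), 0.9)               # recall
  expect_lte(mean(!called %in% truth), 0.1)              # empirical FDR
})

test_that("PAM at zero shrinkage equals plain nearest centroids", {
  set.seed(10)
  n <- 40
  labels <- rep(1:2, each = n / 2)
  X <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:n)))
  X[1:5, labels == 2] <- X[1:5, labels == 2] + 3
  sig <- pam_train(expression_matrix(X), labels, delta_grid = 0, cv_folds = 4,
                   seed = 1)
  pred <- pam_predict(sig, expression_matrix(X), min_overlap = 0.5)
  # plain nearest centroid in (s + s0)-standardized space
  fit <- stromaMR:::pam_fit_centroids(X, labels)
  sc <- fit$s + fit$s0
  d1 <- colSums(((X - fit$centroids[, 1]) / sc)^2)
  d2 <- colSums(((X - fit$centroids[, 2]) / sc)^2)
  expect_identical(unname(pred), unname(fit$classes[1 + (d2 < d1)]))
})

test_that("excessive shrinkage empties the signature with an error", {
  set.seed(11)
  X <- matrix(rnorm(200), 10, 20,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  labels <- rep(1:2, each = 10)
  expect_error(pam_train(expression_matrix(X), labels, delta_grid = 1e6,
                         cv_folds = 4, seed = 1), "empty")
})

test_that("PAM achieves low CV error and recovers planted markers on the default cohort", {
  co <- generate_cohort(cohort_config())
  X <- co$expression
  labels <- co$true_subtype
  sam <- sam_multiclass(X, labels, n_permutations = 50, seed = 2)
  sel <- sam$gene[sam$q < 0.05]
  sig <- pam_train(X[sel, , drop = FALSE], labels, cv_folds = 5, seed = 2)
  expect_lte(min(sig$cv_error_curve$cv_error), 0.05)
  # re-predicting the training samples reproduces the resubstitution error
  pred <- pam_predict(sig, X)
  expect_equal(mean(pred != labels), sig$resubstitution_error)
  # planted stromal-program genes dominate the mesenchymal/immunoreactive up lists
  up_all <- unlist(lapply(sig$up_sets, function(s) s$members))
  planted <- c(co$mese_signature$members, co$immu_signature$members)
  expect_gte(mean(planted %in% up_all), 0.8)
})

test_that("a trained classifier transfers to a fresh cohort from the same generator", {
  co <- generate_cohort(cohort_config(seed = 1))
  sam <- sam_multiclass(co$expression, co$true_subtype, n_permutations = 50, seed = 2)
  sel <- sam$gene[sam$q < 0.05]
  sig <- pam_train(co$expression[sel, , drop = FALSE], co$true_subtype,
                   cv_folds = 5, seed = 2)
  co2 <- generate_cohort(cohort_config(seed = 99))
  pred <- pam_predict(sig, co2$expression)
  expect_gte(adjusted_rand_index(pred, co2$true_subtype), 0.8)
})

test_that("prediction refuses matrices missing too much of the signature", {
  set.seed(12)
  X <- matrix(rnorm(40 * 30), 40, 30,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:30)))
  labels <- rep(1:2, each = 15)
  X[1:10, labels == 2] <- X[1:10, labels == 2] + 3
  sig <- pam_train(expression_matrix(X), labels, cv_folds = 3, seed = 1)
  small <- X[setdiff(rownames(X), sig$signature_genes[-1]), , drop = FALSE]
  expect_error(pam_predict(sig, small), "signature genes present")
})
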