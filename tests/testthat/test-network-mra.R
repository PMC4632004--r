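test_that("mutual information is symmetric, non-negative, and matches the Gaussian closed form", {
  set.seed(1)
  x <- rnorm(5000); y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(5000)
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  est <- mutual_information(x, y)
  expect_gte(est, 0)
  expect_lt(abs(est - (-0.5 * log(1 - 0.8^2))), 0.08)

  # independence: estimate close to the permutation-mean baseline
  z <- rnorm(5000)
  base <- mean(vapply(1:20, function(i) {
    set.seed(100 + i); mutual_information(x, sample(z)) }, numeric(1)))
  expect_lt(mutual_information(x, z) - base, 0.01)

  expect_error(mutual_information(x, y[-1]), "equal length")
  expect_error(mutual_information(rep(1, 100), rnorm(100)), "constant")
  expect_error(mutual_information(rnorm(10), rnorm(10)), "at least 20")
})

test_that("regulon inference recovers planted edges and controls false edges", {
  # admixture-free cohort: non-planted pairs are genuinely independent, so
  # the edge-level FDR contract of the permutation test is testable directly
  co <- generate_cohort(cohort_config(n_genes = 150, n_samples = 150,
                                      n_tfs = 6, targets_per_tf = 10,
                                      n_mese_tfs = 3, n_immu_tfs = 2,
                                      n_markers_per_subtype = 10,
                                      stromal_fraction_range = c(0, 0),
                                      seed = 6))
  X <- co$expression
  net <- infer_regulons(X, co$tf_list, n_permutations = 100, bh_alpha = 0.01,
                        seed = 2)
  ed <- network_edges(net)
  truth <- unlist(lapply(co$true_regulons, function(r) paste(r$tf, r$targets)))
  found <- paste(ed$tf, ed$target)
  expect_gte(mean(truth %in% found), 0.9)
  expect_lte(mean(!found %in% truth), 2 * 0.01 + 0.02)  # binomial slack on 60 edges

  # determinism
  net2 <- infer_regulons(X, co$tf_list, n_permutations = 100, bh_alpha = 0.01,
                         seed = 2)
  expect_identical(network_edges(net2), ed)

  expect_error(infer_regulons(X, c("absent1", "absent2")), "no transcription factor")
})

test_that("no structure means (almost) no edges", {
  set.seed(3)
  X <- matrix(rnorm(100 * 60), 100, 60,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:60)))
  net <- infer_regulons(expression_matrix(X), rownames(X)[1:5],
                        n_permutations = 100, bh_alpha = 0.01, seed = 4)
  n_tests <- 5 * 99
  expect_lte(nrow(network_edges(net)), ceiling(0.01 * n_tests))
})

test_that("bootstrap support separates deterministic, strong and weak edges", {
  set.seed(5)
  n <- 120
  tf <- rnorm(n)
  X <- rbind(TF1 = tf,
             COPY = tf,                                   # deterministic dependence
             STRONG = 0.8 * tf + 0.6 * rnorm(n),
             WEAK = 0.45 * tf + sqrt(1 - 0.45^2) * rnorm(n),
             matrix(rnorm(20 * n), 20, n,
                    dimnames = list(sprintf("g%02d", 1:20), NULL)))
  colnames(X) <- sprintf("s%03d", seq_len(n))
  Xm <- expression_matrix(X)
  net <- infer_regulons(Xm, "TF1", n_permutations = 200, bh_alpha = 0.1, seed = 1)
  expect_true(all(c("COPY", "STRONG", "WEAK") %in% network_edges(net)$target))
  bs <- bootstrap_filter(Xm, net, n_bootstraps = 60, support_threshold = 0,
                         seed = 2)
  sup <- network_edges(bs)
  expect_equal(sup$bootstrap_support[sup$target == "COPY"], 1.0)
  expect_gt(sup$bootstrap_support[sup$target == "STRONG"],
            sup$bootstrap_support[sup$target == "WEAK"])
  # support_threshold = 0 keeps the edge set unchanged
  expect_setequal(paste(sup$tf, sup$target),
                  paste(network_edges(net)$tf, network_edges(net)$target))
})

test_that("DPI removes the weakest edge of a fully connected triplet", {
  reg <- list(
    A = list(tf = "A", targets = c("B", "t"),
             mi = c(B = 0.5, t = 0.1), mode = c(B = 1L, t = 1L),
             bootstrap_support = c(B = 1, t = 1)),
    B = list(tf = "B", targets = "t",
             mi = c(t = 0.4), mode = c(t = 1L), bootstrap_support = c(t = 1)))
  net <- stromaMR:::new_network(reg, universe = c("A", "B", "t"))
  pruned <- apply_dpi(net, 0)
  ed <- network_edges(pruned)
  expect_setequal(paste(ed$tf, ed$target), c("A B", "B t"))
  # large tolerance disables pruning entirely
  loose <- network_edges(apply_dpi(net, 0.99))
  expect_equal(nrow(loose), 3)
  expect_error(apply_dpi(net, -0.1), "epsilon")
})

test_that("DPI agrees with a brute-force triplet enumerator on random networks", {
  for (i in 1:50) {
    net <- random_network(n_nodes = sample(10:30, 1), n_tfs = sample(3:6, 1),
                          seed = 1000 + i)
    eps <- sample(c(0, 0.1, 0.3), 1)
    ours <- network_edges(apply_dpi(net, eps))
    oracle <- dpi_oracle(network_edges(net), eps)
    expect_setequal(paste(ours$tf, ours$target),
                    paste(oracle$tf, oracle$target))
  }
})

test_that("pruning is monotone: DPI output within bootstrap output within raw network", {
  co <- generate_cohort(cohort_config(n_genes = 150, n_samples = 120,
                                      n_tfs = 6, targets_per_tf = 10,
                                      n_mese_tfs = 3, n_immu_tfs = 2,
                                      n_markers_per_subtype = 10, seed = 7))
  X <- co$expression
  raw <- infer_regulons(X, co$tf_list, n_permutations = 50, seed = 1)
  boot <- bootstrap_filter(X, raw, n_bootstraps = 30, seed = 2)
  dpi <- apply_dpi(boot, 0)
  key <- function(n) paste(network_edges(n)$tf, network_edges(n)$target)
  expect_true(all(key(boot) %in% key(raw)))
  expect_true(all(key(dpi) %in% key(boot)))
})

test_that("hypergeometric MRA p-values equal exact combinatorial enumeration", {
  net_for <- function(K, universe, targets) {
    reg <- list(TF = list(tf = "TF", targets = targets,
                          mi = setNames(rep(0.5, K), targets),
                          mode = setNames(rep(1L, K), targets),
                          bootstrap_support = setNames(rep(1, K), targets)))
    stromaMR:::new_network(reg, universe = universe)
  }
  # worked instance: N=100, K=10, n=20, k=5
  universe <- sprintf("u%03d", 1:100)
  targets <- universe[1:10]
  sig <- gene_set("s", universe[c(1:5, 21:35)])   # overlap exactly 5
  res <- mra(net_for(10, universe, targets), sig, min_regulon_size = 5)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, hyper_tail_oracle(5, 100, 10, 20), tolerance = 1e-12)

  # grid of instances with N <= 60
  set.seed(8)
  for (i in 1:40) {
    N <- sample(20:60, 1)
    universe <- sprintf("u%03d", seq_len(N))
    K <- sample(5:15, 1)
    n <- sample(5:15, 1)
    targets <- sample(universe, K)
    sig <- gene_set("s", sample(universe, n))
    res <- mra(net_for(K, universe, targets), sig, min_regulon_size = 2)
    k <- length(intersect(targets, sig$members))
    expect_equal(res$p, hyper_tail_oracle(k, N, K, n), tolerance = 1e-12)
  }

  # signature = universe is a certainty: k = K, p = 1
  sig_all <- gene_set("all", universe)
  res_all <- mra(net_for(K, universe, targets), sig_all, min_regulon_size = 2)
  expect_equal(res_all$overlap, res_all$regulon_size)
  expect_equal(res_all$p, 1)
})

test_that("MRA adjusted p-values are monotone and null master calls are controlled", {
  co <- generate_cohort(cohort_config(seed = 10))
  X <- co$expression
  net <- infer_regulons(X, co$tf_list, n_permutations = 50, seed = 3)
  res <- mra(net, co$mese_signature, min_regulon_size = 10)
  o <- order(res$p)
  expect_true(all(diff(res$p_adjusted[o]) >= -1e-12))
  expect_true(all(res$p_adjusted >= res$p - 1e-12))
  expect_true(all(res$overlap <= pmin(res$regulon_size, res$signature_size)))

  # random signatures of the same size: master calls at most ~ the FDR level
  set.seed(11)
  n_sig <- length(intersect(co$mese_signature$members, net$universe))
  calls <- vapply(1:200, function(i) {
    rand_sig <- gene_set("r", sample(net$universe, n_sig))
    any(mra(net, rand_sig, min_regulon_size = 10)$is_master)
  }, logical(1))
  expect_lte(mean(calls), 0.05 + 2 * sqrt(0.05 * 0.95 / 200) + 0.02)

  expect_error(mra(net, gene_set("none", c("zz1", "zz2"))), "no genes")
})

test_that("GSEA validation of a master regulator flags its regulon", {
  co <- generate_cohort(cohort_config(seed = 1))
  X <- co$expression
  net <- infer_regulons(X, co$tf_list, n_permutations = 50, seed = 2)
  # differential ranking: mesenchymal samples vs the rest
  mese <- co$true_subtype == "Mesenchymal"
  ranking <- rowMeans(X[, mese]) - rowMeans(X[, !mese])
  res <- gsea_validate_mr(net, "TFM01", ranking, n_permutations = 500, seed = 3)
  expect_gt(res$es, 0)
  expect_lt(res$fdr_q, 0.05)

  # a background TF's regulon is not enriched in the mesenchymal contrast
  res_bg <- gsea_validate_mr(net, "TFB01", ranking, n_permutations = 500, seed = 4)
  expect_gt(res_bg$p, 0.05)

  expect_error(gsea_validate_mr(net, "NOPE", ranking), "not in network")
  empty <- stromaMR:::new_network(
    list(A = list(tf = "A", targets = character(0), mi = numeric(0),
                  mode = integer(0), bootstrap_support = numeric(0))),
    universe = names(ranking))
  expect_error(gsea_validate_mr(empty, "A", ranking), "empty regulon")
})
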