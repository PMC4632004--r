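# Shared fixtures and independent oracles used across the suite.

# small deterministic expression matrix with named genes/samples
toy_expression <- function(n_genes = 10, n_samples = 6, seed = 1,
                           dataset_id = "toy") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, dataset_id = dataset_id)
}

# literal double-loop ssGSEA oracle: weighted in-set ECDF minus out-set ECDF,
# summed over all ranks, computed position by position
ssgsea_oracle <- function(x, genes, members, alpha) {
  n <- length(x)
  ord <- order(-x, genes)
  sorted_genes <- genes[ord]
  hit <- sorted_genes %in% members
  w <- numeric(n)
  for (i in seq_len(n)) if (hit[i]) w[i] <- (n - i + 1)^alpha
  total_w <- sum(w)
  n_out <- n - sum(hit)
  score <- 0
  for (i in seq_len(n)) {
    p_in <- sum(w[seq_len(i)]) / total_w
    p_out <- sum(!hit[seq_len(i)]) / n_out
    score <- score + (p_in - p_out)
  }
  score
}

# exact hypergeometric upper-tail by combinatorial enumeration
hyper_tail_oracle <- function(k, N, K, n) {
  # P[X >= k], X = |overlap| drawing n from N with K marked
  i <- seq(k, min(K, n))
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# brute-force DPI: enumerate every (TF1, TF2, target) triplet over the raw
# edge table, mark minimum-MI edges, remove at the end
dpi_oracle <- function(edges, epsilon) {
  key <- function(a, b) paste(a, b, sep = "|")
  mi <- setNames(edges$mi, key(edges$tf, edges$target))
  tfs <- unique(edges$tf)
  und_mi <- function(a, b) {
    v <- mi[key(a, b)]
    if (is.na(v)) v <- mi[key(b, a)]
    v
  }
  drop <- character(0)
  for (a in tfs) for (b in tfs) {
    if (a >= b) next
    mab <- und_mi(a, b)
    if (is.na(mab)) next
    ta <- edges$target[edges$tf == a]
    tb <- edges$target[edges$tf == b]
    for (t in setdiff(intersect(ta, tb), c(a, b))) {
      vals <- c(mab, mi[key(a, t)], mi[key(b, t)])
      w <- which.min(vals)
      if (vals[w] < (1 - epsilon) * min(vals[-w]))
        drop <- c(drop, switch(w, c(key(a, b), key(b, a)), key(a, t), key(b, t)))
    }
  }
  edges[!key(edges$tf, edges$target) %in% unique(drop), c("tf", "target")]
}

# random small network for DPI cross-checks
random_network <- function(n_nodes, n_tfs, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  tfs <- nodes[seq_len(n_tfs)]
  regulons <- lapply(tfs, function(tf) {
    targets <- sample(setdiff(nodes, tf), sample(2:(n_nodes - 2), 1))
    mi <- setNames(runif(length(targets), 0.05, 1), targets)
    list(tf = tf, targets = targets, mi = mi,
         mode = setNames(sample(c(-1L, 1L), length(targets), TRUE), targets),
         bootstrap_support = setNames(rep(1, length(targets)), targets))
  })
  names(regulons) <- tfs
  stromaMR:::new_network(regulons, universe = nodes, params = list())
}

# small cohort configs reused across tests
small_cohort_config <- function(seed = 1, ...) {
  cohort_config(n_genes = 150, n_samples = 80, n_tfs = 6, targets_per_tf = 10,
                n_mese_tfs = 3, n_immu_tfs = 3, n_markers_per_subtype = 10,
                seed = seed, ...)
}

null_survival_config <- function(seed) {
  cohort_config(n_genes = 120, n_samples = 60, n_tfs = 6, targets_per_tf = 10,
                n_mese_tfs = 3, n_immu_tfs = 3, n_markers_per_subtype = 10,
                survival = list(baseline_hazard = 0.02, beta_mese = 0,
                                beta_immu = 0, censor_rate = 0.2),
                seed = seed)
}
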