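# Reverse engineering of TF regulons from expression by mutual information,
# bootstrap stability filtering, data-processing-inequality (DPI) pruning,
# and master-regulator analysis (MRA) by hypergeometric overlap.

new_network <- function(regulons, universe, params = list()) {
  structure(list(regulons = regulons, universe = universe, params = params),
            class = "transcriptional_network")
}

#' @export
print.transcriptional_network <- function(x, ...) {
  n_edges <- sum(vapply(x$regulons, function(r) length(r$targets), integer(1)))
  cat(sprintf("<transcriptional_network> %d TFs, %d edges, universe of %d genes\n",
              length(x$regulons), n_edges, length(x$universe)))
  invisible(x)
}

#' Flatten a network into an edge table
#' @param network A `transcriptional_network`.
#' @return Data.frame: tf, target, mi, mode, bootstrap_support.
#' @export
network_edges <- function(network) {
  rows <- lapply(network$regulons, function(r) {
    if (length(r$targets) == 0L) return(NULL)
    data.frame(tf = r$tf, target = r$targets,
               mi = unname(r$mi[r$targets]),
               mode = unname(r$mode[r$targets]),
               bootstrap_support = unname(r$bootstrap_support[r$targets]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(tf = character(), target = character(), mi = numeric(),
                      mode = integer(), bootstrap_support = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Equal-frequency bin labels from ranks. Deterministic: ties broken by
# original position. Returns integers in 1..n_bins.
rank_bins <- function(x, n_bins) {
  r <- rank(x, ties.method = "first")
  pmin(floor((r - 1) * n_bins / length(x)) + 1L, n_bins)
}

default_bins <- function(n) max(2L, floor(n^(1 / 3)))

# MI (nats) from a contingency table of two bin-label vectors.
mi_from_bins <- function(bx, by, n_bins) {
  n <- length(bx)
  tab <- tabulate(bx + n_bins * (by - 1L), n_bins * n_bins) / n
  px <- tabulate(bx, n_bins) / n
  py <- tabulate(by, n_bins) / n
  expp <- outer(px, py)
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / expp[nz]))
}

#' Mutual information between two expression vectors
#'
#' Plug-in estimate on equal-frequency bins of the ranks: both vectors are
#' rank-transformed, partitioned into `n_bins` bins of near-equal size, and
#' MI (nats) is computed from the joint bin frequencies.
#'
#' @param x,y Numeric vectors of equal length (>= 20).
#' @param n_bins Number of bins; default `floor(n^(1/3))`, floor 2.
#' @return MI in nats (non-negative, symmetric).
#' @export
mutual_information <- function(x, y, n_bins = default_bins(length(x))) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 20L) stop("need at least 20 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant vector: mutual information undefined")
  mi_from_bins(rank_bins(x, n_bins), rank_bins(y, n_bins), n_bins)
}

# MI of one bin vector against every row of a bin matrix, vectorized over
# rows. `B` is genes x samples of bin labels; `tb` the TF's bin labels.
mi_profile <- function(B, tb, n_bins) {
  n <- ncol(B)
  mi <- numeric(nrow(B))
  row_counts <- matrix(0L, nrow(B), n_bins)          # per-gene bin margins
  for (i in seq_len(n_bins)) row_counts[, i] <- rowSums(B == i)
  acc <- numeric(nrow(B))
  for (j in seq_len(n_bins)) {
    cols <- which(tb == j)
    qj <- length(cols) / n
    if (qj == 0) next
    Bj <- B[, cols, drop = FALSE]
    for (i in seq_len(n_bins)) {
      cnt <- rowSums(Bj == i)
      p <- cnt / n
      pi_m <- row_counts[, i] / n
      term <- ifelse(cnt > 0, p * log(p / (pi_m * qj)), 0)
      acc <- acc + term
    }
  }
  acc
}

#' Infer TF regulons by mutual information with a permutation null
#'
#' For each transcription factor, MI to every other gene is computed on
#' rank-binned expression; the null distribution comes from shuffling the
#' TF's profile (one shuffled-profile MI sweep per permutation, pooled
#' across targets), p-values are Benjamini-Hochberg adjusted within each
#' TF's family of tests, and edges with adjusted p below `bh_alpha` are
#' kept. The interaction mode is the sign of the Spearman correlation.
#'
#' @param X An [expression_matrix()].
#' @param tf_list Character vector of TF gene symbols (entries absent from
#'   `X` are ignored; none present is an error).
#' @param n_permutations Shuffles of the TF profile per TF.
#' @param bh_alpha Adjusted-p threshold for keeping an edge.
#' @param seed Integer seed.
#' @param n_bins MI bin count.
#' @return A `transcriptional_network`; params records the per-TF critical
#'   MI (smallest MI among accepted edges) used by [bootstrap_filter()].
#' @export
infer_regulons <- function(X, tf_list, n_permutations = 100, bh_alpha = 0.01,
                           seed = 1L, n_bins = default_bins(ncol(X))) {
  genes <- rownames(X)
  tfs <- intersect(tf_list, genes)
  if (!length(tfs)) stop("no transcription factor from `tf_list` present in X")
  n <- ncol(X)
  B <- t(apply(X, 1L, rank_bins, n_bins = n_bins))
  storage.mode(B) <- "integer"
  rng <- local_rng(seed)
  crit_mi <- stats::setNames(rep(Inf, length(tfs)), tfs)
  regulons <- vector("list", length(tfs))
  names(regulons) <- tfs
  for (tf in tfs) {
    others <- setdiff(genes, tf)
    Bo <- B[others, , drop = FALSE]
    obs <- mi_profile(Bo, B[tf, ], n_bins)
    null_pool <- numeric(0)
    for (p in seq_len(n_permutations)) {
      tb <- B[tf, rng$sample_int(n)]
      null_pool <- c(null_pool, mi_profile(Bo, tb, n_bins))
    }
    null_sorted <- sort(null_pool)
    n_null <- length(null_sorted)
    ge <- n_null - findInterval(obs - 1e-12, null_sorted)  # #null >= obs
    pval <- (1 + ge) / (1 + n_null)
    padj <- stats::p.adjust(pval, method = "BH")
    keep <- which(padj < bh_alpha)
    targets <- others[keep]
    mode <- integer(0)
    if (length(targets)) {
      mode <- vapply(targets, function(g) {
        s <- stats::cor(X[tf, ], X[g, ], method = "spearman")
        if (is.na(s) || s >= 0) 1L else -1L
      }, integer(1))
      # critical MI of the re-test: the null quantile reproducing the
      # largest raw p accepted by BH (an MI strictly above it passes)
      p_star <- max(pval[keep])
      m_star <- max(0L, floor(p_star * (1 + n_null)) - 1L)
      crit_mi[tf] <- if (m_star >= n_null) 0 else null_sorted[n_null - m_star]
    }
    regulons[[tf]] <- list(
      tf = tf, targets = targets,
      mi = stats::setNames(obs[keep], targets),
      mode = stats::setNames(mode, targets),
      bootstrap_support = stats::setNames(rep(NA_real_, length(targets)), targets))
  }
  new_network(regulons, universe = genes,
              params = list(n_permutations = n_permutations, bh_alpha = bh_alpha,
                            n_bins = n_bins, seed = seed, crit_mi = crit_mi))
}

#' Remove bootstrap-unstable edges
#'
#' Samples are resampled with replacement `n_bootstraps` times; on each
#' replicate every retained edge is re-tested (its MI on the resampled data
#' must reach the TF's critical MI from the original permutation test), and
#' edges supported in fewer than `support_threshold` of replicates are
#' dropped. Support is recorded on the surviving edges.
#'
#' @param X The expression matrix the network was inferred from.
#' @param network Output of [infer_regulons()].
#' @param n_bootstraps Number of resamples (>= 2).
#' @param support_threshold Minimum fraction of replicates an edge must pass.
#' @param seed Integer seed.
#' @return The filtered `transcriptional_network`.
#' @export
bootstrap_filter <- function(X, network, n_bootstraps = 100,
                             support_threshold = 0.95, seed = 1L) {
  if (n_bootstraps < 2L) stop("n_bootstraps must be >= 2")
  n_bins <- network$params$n_bins %||% default_bins(ncol(X))
  crit <- network$params$crit_mi
  rng <- local_rng(seed)
  n <- ncol(X)
  tfs <- names(network$regulons)
  pass <- lapply(network$regulons, function(r)
    stats::setNames(numeric(length(r$targets)), r$targets))
  for (b in seq_len(n_bootstraps)) {
    idx <- rng$sample_int(n, n, replace = TRUE)
    Xb <- X[, idx, drop = FALSE]
    Bb <- t(apply(Xb, 1L, rank_bins, n_bins = n_bins))
    storage.mode(Bb) <- "integer"
    for (tf in tfs) {
      r <- network$regulons[[tf]]
      if (!length(r$targets)) next
      mi_b <- mi_profile(Bb[r$targets, , drop = FALSE], Bb[tf, ], n_bins)
      thr <- if (!is.null(crit) && is.finite(crit[[tf]])) crit[[tf]] else min(r$mi)
      pass[[tf]] <- pass[[tf]] + as.numeric(mi_b > thr)
    }
  }
  regulons <- lapply(network$regulons, function(r) {
    if (!length(r$targets)) return(r)
    support <- pass[[r$tf]] / n_bootstraps
    keep <- names(support)[support >= support_threshold]
    list(tf = r$tf, targets = keep,
         mi = r$mi[keep], mode = r$mode[keep],
         bootstrap_support = support[keep])
  })
  new_network(regulons, network$universe,
              c(network$params, list(n_bootstraps = n_bootstraps,
                                     support_threshold = support_threshold)))
}

#' Prune redundant edges with the data-processing inequality
#'
#' For every triplet (TF1, TF2, t) in which the TF-TF edge and both TF-target
#' edges exist, the minimum-MI edge is marked for removal when its MI is
#' below `(1 - epsilon)` times the smaller of the other two. A single pass
#' over all triplets is made against the frozen (original) MI values; marked
#' edges are removed at the end.
#'
#' @param network A `transcriptional_network`.
#' @param epsilon DPI tolerance in `[0, 1]`; 0 is strictest.
#' @return The pruned network.
#' @export
apply_dpi <- function(network, epsilon = 0) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  edges <- network_edges(network)
  if (!nrow(edges)) return(network)
  ekey <- function(tf, tg) paste(tf, tg, sep = "\r")
  mi_of <- stats::setNames(edges$mi, ekey(edges$tf, edges$target))
  # undirected lookup between two TFs: either direction may carry the edge
  tf_names <- names(network$regulons)
  get_mi <- function(a, b) {
    v <- mi_of[ekey(a, b)]
    if (is.na(v)) v <- mi_of[ekey(b, a)]
    v
  }
  drop <- character(0)
  for (i in seq_along(tf_names)) for (j in seq_along(tf_names)) {
    if (i >= j) next
    tf1 <- tf_names[i]; tf2 <- tf_names[j]
    m12 <- get_mi(tf1, tf2)
    if (is.na(m12)) next
    common <- intersect(network$regulons[[tf1]]$targets,
                        network$regulons[[tf2]]$targets)
    common <- setdiff(common, c(tf1, tf2))
    for (t in common) {
      m1t <- mi_of[ekey(tf1, t)]
      m2t <- mi_of[ekey(tf2, t)]
      mis <- c(m12, m1t, m2t)
      w <- which.min(mis)
      if (mis[w] < (1 - epsilon) * min(mis[-w])) {
        drop <- c(drop, switch(w,
          c(ekey(tf1, tf2), ekey(tf2, tf1)),
          ekey(tf1, t),
          ekey(tf2, t)))
      }
    }
  }
  drop <- unique(drop)
  regulons <- lapply(network$regulons, function(r) {
    keep <- r$targets[!ekey(r$tf, r$targets) %in% drop]
    list(tf = r$tf, targets = keep, mi = r$mi[keep], mode = r$mode[keep],
         bootstrap_support = r$bootstrap_support[keep])
  })
  new_network(regulons, network$universe,
              c(network$params, list(dpi_epsilon = epsilon)))
}

#' Master-regulator analysis by hypergeometric overlap
#'
#' Each TF whose regulon has at least `min_regulon_size` targets inside the
#' universe is tested for overlap with the signature: with N the universe
#' size, K the regulon size, n the signature size (inside the universe) and
#' k the observed overlap, p = P[X >= k] under Hypergeometric(N, K, n).
#' P-values are Benjamini-Hochberg adjusted across tested TFs; a TF is
#' called a master regulator when the adjusted p falls below `fdr`.
#'
#' @param network A `transcriptional_network`.
#' @param signature A [gene_set()] of subtype signature genes.
#' @param min_regulon_size Smallest testable regulon (default 15).
#' @param fdr Adjusted-p threshold for the master-regulator call.
#' @param universe Optional gene universe; defaults to the network's.
#' @return Data.frame: tf, regulon_size, signature_size, universe_size,
#'   overlap, p, p_adjusted, is_master.
#' @export
mra <- function(network, signature, min_regulon_size = 15, fdr = 0.05,
                universe = network$universe) {
  sig <- intersect(signature$members, universe)
  if (!length(sig))
    stop("signature '", signature$name, "' has no genes in the universe")
  N <- length(universe)
  rows <- lapply(network$regulons, function(r) {
    targ <- intersect(r$targets, universe)
    K <- length(targ)
    if (K < min_regulon_size) return(NULL)
    k <- length(intersect(targ, sig))
    p <- stats::phyper(k - 1, length(sig), N - length(sig), K, lower.tail = FALSE)
    data.frame(tf = r$tf, regulon_size = K, signature_size = length(sig),
               universe_size = N, overlap = k, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(tf = character(), regulon_size = integer(),
                      signature_size = integer(), universe_size = integer(),
                      overlap = integer(), p = numeric(),
                      p_adjusted = numeric(), is_master = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out$is_master <- out$p_adjusted < fdr
  out[order(out$p), ]
}

#' Validate a master-regulator call with GSEA
#'
#' Runs [gsea()] with the TF's regulon target set as the gene set over a
#' supplied differential ranking (e.g. subtype vs rest contrast).
#'
#' @param network A `transcriptional_network`.
#' @param tf TF symbol present in the network.
#' @param ranking Named signed ranking vector.
#' @param ... Passed to [gsea()].
#' @return One-row data.frame from [gsea()].
#' @export
gsea_validate_mr <- function(network, tf, ranking, ...) {
  r <- network$regulons[[tf]]
  if (is.null(r)) stop("TF '", tf, "' not in network")
  if (!length(r$targets)) stop("TF '", tf, "' has an empty regulon")
  gsea(ranking, gene_set(paste0("regulon_", tf), r$targets), ...)
}
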