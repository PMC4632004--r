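# Rank-based enrichment engines: GSEA on a signed ranking, single-sample
# GSEA (ssGSEA) on expression columns, per-dataset score normalization, and
# the stromal/immune/combined scoring built from ssGSEA.

# Core running-sum statistic from sorted hit positions. `hit_pos` are the
# 1-based positions of set members in the ranked list (ascending), `w` the
# corresponding non-negative hit weights, `n` the total list length. The
# extreme of the running sum is attained either at a hit (after its
# increment) or immediately before a hit (after the preceding misses), so
# only O(|set|) candidates need checking.
es_from_hits <- function(hit_pos, w, n) {
  m <- length(hit_pos)
  if (m == 0L) stop("gene set has no members in the ranking")
  wsum <- sum(w)
  miss_den <- n - m
  p_in <- cumsum(w) / (if (wsum > 0) wsum else 1)
  if (miss_den == 0L) {           # set covers the whole list
    return(max(p_in))
  }
  p_out_at <- (hit_pos - seq_len(m)) / miss_den           # misses seen at hit i
  p_out_before <- (hit_pos - 1L - (seq_len(m) - 1L)) / miss_den
  up <- p_in - p_out_at
  down <- c(0, p_in[-m]) - p_out_before
  hi <- max(up)
  lo <- min(down)
  if (hi >= -lo) hi else lo
}

#' Gene Set Enrichment Analysis over a signed ranking
#'
#' Weighted Kolmogorov-Smirnov-like running sum: hits increment by
#' `|r|^weight_p` (normalized), misses decrement by `1/(N - Nh)`; the
#' enrichment score (ES) is the maximum deviation of the running sum.
#' Significance comes from gene-label permutation (random sets of the same
#' size), NES is the ES divided by the mean absolute null ES of matching
#' sign, and FDR q-values are Benjamini-Hochberg across the gene sets of the
#' call.
#'
#' @param ranking Named numeric vector, gene -> signed ranking statistic
#'   (e.g. a differential-expression contrast). Sorted internally.
#' @param gene_sets A [gene_set()] or list of them.
#' @param weight_p Hit-weight exponent (0 = classic Kolmogorov-Smirnov, 1 =
#'   weighted).
#' @param n_permutations Gene-label permutations for the null.
#' @param seed Integer seed for the permutation null.
#' @param min_overlap Minimum genes shared between set and ranking.
#' @return A data.frame with one row per set: set, size, es, nes, p, fdr_q,
#'   and a `leading_edge` list-column.
#' @export
gsea <- function(ranking, gene_sets, weight_p = 1, n_permutations = 1000,
                 seed = 1L, min_overlap = 3L) {
  if (is.null(names(ranking))) stop("`ranking` must be a named vector")
  if (inherits(gene_sets, "gene_set")) gene_sets <- list(gene_sets)
  ord <- order(ranking, decreasing = TRUE)
  genes <- names(ranking)[ord]
  r <- as.numeric(ranking)[ord]
  n <- length(r)
  absw <- abs(r)^weight_p
  rows <- lapply(gene_sets, function(gs) {
    hit <- which(genes %in% gs$members)
    if (length(hit) < min_overlap)
      stop("gene set '", gs$name, "' overlaps ranking by ", length(hit),
           " genes (< ", min_overlap, ")")
    es <- es_from_hits(hit, absw[hit], n)
    m <- length(hit)
    null_es <- numeric(n_permutations)
    rng <- local_rng(seed)
    for (b in seq_len(n_permutations)) {
      hp <- sort(rng$sample_int(n, m))
      null_es[b] <- es_from_hits(hp, absw[hp], n)
    }
    same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    # leading edge: hits up to (including) the running-sum extreme
    le <- leading_edge(genes, hit, absw, n, es)
    list(set = gs$name, size = m, es = es, nes = nes, p = p, leading_edge = le)
  })
  out <- data.frame(set = vapply(rows, `[[`, character(1), "set"),
                    size = vapply(rows, `[[`, integer(1), "size"),
                    es = vapply(rows, `[[`, numeric(1), "es"),
                    nes = vapply(rows, `[[`, numeric(1), "nes"),
                    p = vapply(rows, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  out$fdr_q <- stats::p.adjust(out$p, method = "BH")
  out$leading_edge <- lapply(rows, `[[`, "leading_edge")
  out
}

leading_edge <- function(genes, hit, absw, n, es) {
  m <- length(hit)
  miss_den <- n - m
  p_in <- cumsum(absw[hit]) / max(sum(absw[hit]), .Machine$double.eps)
  if (miss_den == 0L) return(genes[hit])
  up <- p_in - (hit - seq_len(m)) / miss_den
  down <- c(0, p_in[-m]) - (hit - 1L - (seq_len(m) - 1L)) / miss_den
  if (es >= 0) genes[hit[seq_len(which.max(up))]]
  else genes[hit[seq(which.min(down), m)]]
}

#' Single-sample GSEA scores
#'
#' For each sample, genes are ranked by expression (descending; ties broken
#' by gene id so the score is deterministic), hits are weighted by
#' `rank^alpha` where the top gene carries rank N, and the score is the sum
#' over all ranks of the difference between the weighted in-set empirical
#' CDF and the out-of-set ECDF.
#'
#' @param X An [expression_matrix()] (or plain named matrix).
#' @param gene_set A [gene_set()].
#' @param alpha Rank-weight exponent (default 0.25).
#' @param min_overlap Minimum genes shared between set and matrix.
#' @return A data.frame of per-sample scores: sample_id, raw, normalized
#'   (NA until [normalize_scores()]), dataset_id.
#' @export
ssgsea <- function(X, gene_set, alpha = 0.25, min_overlap = 3L) {
  genes <- rownames(X)
  hit_mask <- genes %in% gene_set$members
  m <- sum(hit_mask)
  if (m < min_overlap)
    stop("gene set '", gene_set$name, "' overlaps expression by ", m,
         " genes (< ", min_overlap, ")")
  n <- nrow(X)
  raw <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (length(unique(x)) == 1L)
      warning("sample '", colnames(X)[j],
              "' has constant expression; score computed on tie-broken ranks")
    ord <- order(-x, genes)              # descending, ties by gene id
    hits <- which(hit_mask[ord])
    w <- (n - hits + 1)^alpha            # descending rank weight, top gene = N
    p_in_steps <- numeric(n)
    p_in_steps[hits] <- w / sum(w)
    p_out_steps <- numeric(n)
    p_out_steps[-hits] <- 1 / (n - m)
    sum(cumsum(p_in_steps) - cumsum(p_out_steps))
  }, numeric(1))
  data.frame(sample_id = colnames(X), raw = raw, normalized = NA_real_,
             dataset_id = dataset_id(X), stringsAsFactors = FALSE)
}

#' Normalize sample scores within each dataset
#'
#' Default (`"range"`) divides each raw score by the absolute difference
#' between the dataset's minimum and maximum raw score, so scores become
#' comparable across cohorts before pooling. The `"minmax"` variant
#' additionally subtracts the minimum, mapping scores to the unit interval.
#' Either way the within-dataset rank order is unchanged.
#'
#' @param scores Data.frame from [ssgsea()] (columns raw, dataset_id).
#' @param variant `"range"` (raw / (max - min)) or `"minmax"`
#'   ((raw - min) / (max - min)).
#' @return The input with `normalized` filled in.
#' @export
normalize_scores <- function(scores, variant = c("range", "minmax")) {
  variant <- match.arg(variant)
  for (ds in unique(scores$dataset_id)) {
    idx <- scores$dataset_id == ds
    r <- scores$raw[idx]
    span <- max(r) - min(r)
    if (span == 0)
      stop("dataset '", ds, "' has constant raw scores; cannot normalize")
    scores$normalized[idx] <- if (variant == "range") r / span else (r - min(r)) / span
  }
  scores
}

#' Stromal, immune and combined enrichment scores
#'
#' ssGSEA scores for a stromal and an immune gene set plus their sum, an
#' expression-only proxy for the infiltrating non-tumor content of each
#' sample (high combined score = low tumor purity).
#'
#' @param X An [expression_matrix()].
#' @param stromal_set,immune_set [gene_set()] objects.
#' @param alpha ssGSEA rank-weight exponent.
#' @return Data.frame: sample_id, stromal, immune, combined.
#' @export
estimate_scores <- function(X, stromal_set, immune_set, alpha = 0.25) {
  s <- ssgsea(X, stromal_set, alpha = alpha)
  i <- ssgsea(X, immune_set, alpha = alpha)
  data.frame(sample_id = s$sample_id, stromal = s$raw, immune = i$raw,
             combined = s$raw + i$raw, stringsAsFactors = FALSE)
}

# Small self-contained RNG wrapper: isolates seeded draws from the global
# stream so library code never perturbs a caller's RNG state.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    sample_int = function(n, size = n, replace = FALSE)
      with_state(sample.int(n, size, replace = replace)),
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    rexp = function(n, rate = 1) with_state(stats::rexp(n, rate)),
    with_state = with_state
  )
}
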