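# stromaMR

Bulk tumor expression cohorts of high-grade serous ovarian carcinoma
(HGS-OvCa) split into four molecular subtypes — Differentiated,
Proliferative, Mesenchymal and Immunoreactive — yet two of those classes are
driven less by the tumor cells than by the stroma admixed with them.
`stromaMR` implements, end to end, the analysis chain that makes this case
and turns it into a prognostic tool:

1. **Consensus subtyping** — non-negative matrix factorization (NMF) and
   k-means consensus clustering over column subsamples, silhouette-width
   filtering of non-representative samples, multiclass SAM gene selection
   and a nearest-shrunken-centroid (PAM) subtype classifier.
2. **Enrichment scoring** — GSEA on signed rankings, single-sample GSEA
   (ssGSEA), per-dataset score normalization, and ESTIMATE-style
   stromal/immune/combined scores as an expression-only proxy of tumor
   purity.
3. **Network inference and master-regulator analysis (MRA)** — TF regulons
   by mutual information (equal-frequency rank binning) with a permutation
   null and BH correction, bootstrap stability filtering, data-processing-
   inequality (DPI) pruning, and hypergeometric overlap of each regulon
   with a subtype signature:
   for a universe of `N` genes, a regulon of size `K`, a signature of size
   `n` and overlap `k`, `p = P[X >= k]` with `X ~ Hypergeom(N, K, n)`.
4. **Prognosis** — per-sample MR compound scores (ssGSEA of the 6-gene
   mesenchymal and 10-gene immunoreactive MR sets), median dichotomization
   within each dataset, the three-group stratification
   `immu+mese-` / `mixed` / `immu-mese+`, Kaplan-Meier curves, log-rank
   tests, univariate Cox hazard ratios (forest tables), and pooled
   meta-analysis across cohorts.

Because the original cohorts require controlled-access downloads, the
package ships a **synthetic-cohort generator** with planted ground truth —
subtype labels, TF regulons of known strength and mode, per-sample stromal
fractions carrying the two signature programs, paired designs
(stroma/epithelium, primary/PDX, primary/metastasis, treated/untreated) and
survival with known log-hazard coefficients — so every stage can be
validated by parameter recovery. The 16-symbol MR signature (ZEB1, ZEB2,
SNAI2, PRRX1, AEBP1, HOPX; IRF7, IRF9, IKZF1, IKZF3, BATF, ETV7, BTN3A3,
SP140, HCLS1, TFEC) ships as `inst/extdata/mr_signature.gmt`.

## Worked example

```r
library(stromaMR)

cohort <- generate_cohort(cohort_config(seed = 1))      # 500 x 200, 4 subtypes
X <- cohort$expression

# subtype recovery
cc  <- consensus_cluster(X, 4, method = "kmeans", n_reps = 30, seed = 7)[[1]]
sil <- silhouette_filter(1 - cc$consensus_matrix, cc$labels)
adjusted_rand_index(cc$labels[sil$core_samples],
                    cohort$true_subtype[sil$core_samples])
#> [1] 0.9608969

# regulons and master regulators
net <- infer_regulons(X, cohort$tf_list, seed = 3)
net <- apply_dpi(bootstrap_filter(X, net, seed = 4), 0)
res <- mra(net, cohort$mese_signature)
res$tf[res$is_master]
#> [1] "TFM01" "TFM03" "TFM06" "TFM02" "TFM05" "TFM04"

# prognostic stratification
sc <- score_and_stratify(X, cohort$mese_mrs, cohort$immu_mrs)
m  <- merge(sc, as.data.frame(cohort$survival), by = "sample_id")
logrank_test(m$time, m$event, m$group)$p
#> [1] 0.0001461697
```

The ARI says the consensus clusters reproduce the planted subtypes almost
exactly after core-sample filtering; the MRA call list is exactly the six
planted mesenchymal master regulators; and the three prognostic groups
separate survival at p < 0.001, in the planted direction (mesenchymal
activation harmful, immunoreactive protective).

The numbered scripts under `analysis/` run the same chain as a narrative
workflow (simulate, subtype, stromal scores, network/MRA, prognosis) and
write their tables under `results/`.

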