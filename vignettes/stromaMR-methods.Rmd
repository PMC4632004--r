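---
title: "Stromal master regulators of expression subtypes: models and methods"
author: "stromaMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stromal master regulators of expression subtypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stromaMR` implements an analysis chain for bulk tumor expression cohorts:
consensus molecular subtyping, stromal-admixture scoring, reverse
engineering of transcription-factor regulons, master-regulator calls, and a
compound-score prognostic stratification. This vignette is the package's
account of the underlying models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does and
does not establish.

## The scientific model

Bulk tumor expression is a mixture. Writing $f_j \in [0,1]$ for the
stromal fraction of sample $j$, the observed profile is modeled as
$(1-f_j)\,\mathrm{epithelium} + f_j\,\mathrm{stroma}$. Two of the four
expression subtypes of high-grade serous ovarian carcinoma (Mesenchymal and
Immunoreactive) are, on this view, largely read-outs of stromal content:
their signature genes live in the stromal component, their samples carry
systematically lower tumor purity, and their defining transcription factors
("master regulators", MRs) are stroma-expressed. The prognostic claim is
that ssGSEA compound scores of the 6 mesenchymal and 10 immunoreactive MRs,
median-dichotomized and combined into three groups (`immu+mese-`, `mixed`,
`immu-mese+`), order patient survival.

## Consensus subtyping

`nmf_factorize()` fits $V \approx WH$ by Lee–Seung multiplicative updates
under the Frobenius objective after shifting every gene by its row minimum
(the shift preserves within-gene ordering; a column-scaling alternative was
considered and rejected because it distorts relative fold changes).
Iterations stop when the relative objective decrease falls below `tol`
(default 1e-6, capped at 500 iterations); the objective is asserted
non-increasing at every step, and the best of `n_restarts` random
initializations wins. The $W$/$H$ scale ambiguity is resolved by
normalizing $W$'s columns to unit sum before reading labels as the argmax
metagene of $H$.

`consensus_cluster()` repeats clustering on random column subsamples
(default 80%) and records, for every sample pair, the fraction of
co-subsampled replicates in which they co-clustered. Final labels come from
average-linkage hierarchical clustering of $1 - $ consensus; the cophenetic
correlation of that dendrogram against $1-$consensus supports rank
selection. k-means replicates are seeded with k-means++ and keep the best of
10 inner starts. Silhouette widths are computed on $1-$consensus (the
paper-scale analyses leave the choice of dissimilarity open; consensus
distance matches consensus-clustering practice), and samples with
non-positive width are dropped from the core set. Singleton-cluster members
get width 0 and are flagged rather than erroring, so a degenerate cut
cannot crash a pipeline run.

SAM (`sam_multiclass()`) scores each gene with a standardized between-class
contrast $d_i = \sqrt{\sum_k n_k(\bar x_{ik}-\bar x_i)^2/(K-1)}\,/\,(s_i +
s_0)$, where $s_i$ is the pooled within-class SD and the exchangeability
constant $s_0$ is the median of the $s_i$ (the percentile-search variant
adds a stochastic optimization we deliberately avoid; the median keeps the
statistic deterministic). Q-values come from label permutations: at each
threshold the estimated false count is the median permutation count of
$|d^*|$ above it divided by the observed count, clamped to $[0,1]$ and made
monotone by taking, for each gene, the minimum estimate over its own and
all less stringent thresholds (the step-up construction; an earlier draft
monotonized in the opposite direction, which a calibration test caught).

PAM (`pam_train()`) is the nearest-shrunken-centroid classifier:
$d_{ik} = (\bar x_{ik}-\bar x_i)/(m_k(s_i+s_0))$ with $m_k =
\sqrt{1/n_k - 1/n}$, soft-thresholded by $\Delta$; $\Delta$ is chosen by
stratified cross-validation (default 5 folds) with ties broken toward the
largest $\Delta$ — the most parsimonious signature. Class priors are
uniform. Genes with any surviving component form the signature; a gene's
subtype is that of its largest positive component, giving per-subtype
up-regulated lists that feed the MRA. The SAM cutoff feeding PAM (q < 0.05)
and the fold count are configuration, since neither is pinned down at
paper scale.

## Enrichment scoring

`gsea()` uses the weighted Kolmogorov–Smirnov running sum: hits increment
by $|r|^p$ (normalized), misses decrement by $1/(N-N_h)$, ES is the maximum
deviation. Because the module receives a precomputed ranking rather than
sample-level phenotypes, the null permutes gene labels (random sets of the
same size) — a documented deviation from the phenotype-permutation default
of the original method, and the coherent choice for this interface. NES
divides ES by the mean absolute null ES of matching sign; FDR is BH across
the sets in the call.

`ssgsea()` ranks genes within each sample (descending; ties broken by gene
id so scores are platform-independent), weights hits by
$\mathrm{rank}^\alpha$ with the top gene carrying rank $N$, and sums the
difference between the weighted in-set ECDF and the out-of-set ECDF over
all ranks. $\alpha$ defaults to 0.25, the method's canonical exponent.
Scores are normalized within each dataset by dividing by the raw-score
range; the sentence describing this normalization can also be read as
min-subtracting, so both variants are implemented (`normalize_scores()`,
default `"range"`). `estimate_scores()` composes stromal + immune ssGSEA
scores; their sum is the combined score, a monotone proxy for non-tumor
content.

## Network inference and MRA

`mutual_information()` is a plug-in estimate on equal-frequency bins of the
ranks, $\lfloor n^{1/3} \rfloor$ bins (floor 2). Binning on ranks makes the
estimator invariant to monotone transforms and testable against the
Gaussian closed form $-\tfrac12\ln(1-\rho^2)$.

`infer_regulons()` computes MI from each TF to every other gene; the null
shuffles the TF profile, pooling null MI values across targets within a TF
(one sweep per permutation — per-edge nulls would cost a factor of the gene
count for little gain at these sizes). P-values are BH-adjusted within each
TF's family; edges below `bh_alpha` (default 0.01) survive, carrying the
sign of the Spearman correlation as their mode. `bootstrap_filter()`
resamples samples with replacement and re-tests each retained edge: an edge
passes a replicate when its MI on the resampled data exceeds the TF's
critical MI, defined as the null-pool quantile reproducing the BH-accepted
edge set (re-running a full permutation test per replicate would multiply
the cost by the bootstrap count while testing the same hypothesis).
Edges supported in fewer than 95% of replicates are dropped. `apply_dpi()`
then removes, for every fully connected (TF, TF, target) triplet, the
minimum-MI edge when it falls below $(1-\varepsilon)$ times the smaller of
the other two — a single pass against frozen MI values, $\varepsilon = 0$
by default. The pipeline is edge-monotone: DPI output ⊆ bootstrap output ⊆
raw network.

`mra()` tests each regulon of at least `min_regulon_size` targets
(default 15 — hypergeometric tails on very small regulons are unstable)
against a signature by the hypergeometric upper tail, BH-corrected across
tested TFs, with the universe defaulting to the network's target-eligible
genes rather than the whole array. Modes do not enter the overlap count;
the analysis is mode-agnostic and modes are carried for reporting.

## Prognosis

Compound scores are ssGSEA of the two MR sets. Activation is score strictly
above the within-dataset median (ties low — deterministic and
conservative); under independence this yields expected 75%/25%
union/intersection activation fractions, the arithmetic behind the
published 78%/28%. The three groups follow from the two booleans, with
`immu+mese+` and `immu-mese-` retained as subgroups for the both-active
contrast. Survival estimation delegates to the `survival` package:
Kaplan-Meier product-limit curves, the variance-weighted multi-group
log-rank, and univariate Cox fits with Efron tie handling. Meta-analysis
scores, normalizes and dichotomizes within each cohort (the normalization
language is per-dataset; pooled-threshold dichotomization is the other
reading and is not the default), then pools samples for an unstratified
log-rank; a cohort-stratified variant was considered and left out of the
default because single pooled survival curves are the reported object.
Paired comparisons use the Wilcoxon signed-rank with zero differences
dropped (all-zero returns p = 1 with a warning); unpaired use the rank-sum;
all tests two-sided; gene families BH-corrected.

## The synthetic cohort: what it emulates

`generate_cohort()` plants, in order: uniform subtype labels; epithelial
marker blocks per subtype scaled by $1-f$; TF regulons with target
$= \mathrm{mode}\cdot a\cdot \mathrm{TF} + \sqrt{1-a^2}\,\varepsilon$ so
the TF-target correlation is exactly the configured `regulon_strength`;
stromal over-expression of the two planted programs (each program = its MR
TFs plus their targets), proportional to $f$ with weight 1 for the
matching stromal subtype and 0.5 otherwise; and exponential survival with
hazard $\lambda\exp(\beta_m z_m + \beta_i z_i)$ on the standardized
observed program means, with independent exponential censoring whose rate
is solved numerically so the expected censoring fraction equals
`censor_rate`.

Default geometry: 500 genes x 200 samples; 24 TFs (6 mesenchymal MRs, 10
immunoreactive MRs, 8 background) with 18 targets each; 20 epithelial
markers for each of the two epithelium-driven subtypes; noise SD 0.4;
stromal fractions uniform on [0.1, 0.6] with the stroma-associated
subtypes drawing from the upper half; $\lambda = 0.02$/month (median
survival near three years at baseline, realistic for this disease),
$\beta_m = \ln 2$, $\beta_i = -\ln 2$, 30% censoring. Choices worth
flagging:

* **18 targets per regulon** leaves headroom above the MRA testing floor of
  15 after bootstrap pruning removes one or two boundary edges; with
  exactly 15 planted targets a pruned regulon can fall below the floor and
  become untestable — a size artifact, not a recovery failure.
* **Off-program stromal weight 0.5.** Both programs are stroma-borne, so
  every sample's stroma carries some of each; at much lower weights the
  dominant program's bump crowds the weaker program out of the sample's
  rank space and its ssGSEA score is no longer consistently
  stroma-enriched, contradicting the qualitative structure the generator
  is supposed to emulate.
* **Epithelial markers only for the epithelium-driven subtypes** (a config
  knob, `marker_subtypes`). Giving the stromal subtypes epithelial markers
  hands PAM clean low-variance discriminators that displace the stromal
  program genes from the signature and break the MRA overlap — and
  misrepresents the biology the package models.
* **Paired designs share one base-noise draw per pair**: the two members
  describe the same latent tumor at counterfactual stromal fractions
  (pure stroma/epithelium; PDX at $f \approx 0$; metastasis and
  chemotherapy shift $f$ up by 0.15), so paired differences isolate the
  admixture terms.

What passing tests on this generator shows: the estimators recover planted
structure of realistic effect size under Gaussian noise and a linear
mixture. What it does not show: robustness to probe-level artifacts, batch
effects, non-linear regulation, heavy-tailed noise, mouse/human read
ambiguity in PDX data, or misspecified survival models — none of which the
generator attempts to emulate.

## Numerical choices and degenerate inputs

Ranks use `ties.method = "first"` with a stable gene-id order, so every
rank-based quantity is deterministic across platforms. Constant genes are
rejected by the MI estimator, score `d = 0, q = 1` in SAM, and are reported
as missing by the score-gene correlation. Constant samples warn in ssGSEA
and score on tie-broken ranks. Duplicate probes collapse to the
maximum-variance row at read time (common microarray practice; the
alternative — averaging — attenuates bimodal probes). All seeded draws run
through an isolated RNG stream so library calls never perturb the caller's
RNG state.

At the default study conditions, rank-4 NMF spends its metagenes on the
regulon genes' latent variance (456 of 500 genes carry i.i.d. TF noise)
rather than on the subtype blocks, so the default pipeline clusters with
k-means consensus; NMF label recovery is validated on subtype-dominated
conditions (few TFs, markers for all four subtypes, low noise), where it is
exact. This mirrors practice on real arrays, where NMF subtyping operates
on variance-filtered gene subsets.

## Problem sizes used in validation

The test suite and the acceptance script run the full chain on the default
500 x 200 cohort (one hundred permutations and bootstrap replicates in the
network stage), calibration simulations at 2000 replicates for type-I
error, 400 for CI coverage and 200 for hazard-ratio recovery, and paired
designs at the nine-pair scale of the PDX comparison they emulate. These
sizes give the Monte-Carlo estimates standard errors comfortably inside
the asserted bands.

## Known limitations

The generator's mixture is linear and noise Gaussian; MI regulon inference
is binned (no kernel estimator) and pairwise (no conditional MI); the MRA
universe, permutation/bootstrap counts and DPI tolerance are configuration
with defaults, not estimated; survival is exponential with proportional
hazards by construction; and the pipeline does not attempt multivariable
Cox adjustment, competing risks, or time-varying effects.
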