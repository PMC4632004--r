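#!/usr/bin/env Rscript
# Regulatory-network reverse engineering and master-regulator analysis:
# MI regulons with a permutation null, bootstrap stability filtering, DPI
# pruning, then hypergeometric overlap of each regulon with the data-derived
# subtype signatures, and GSEA validation of the calls.

library(stromaMR)

X <- read_expression("results/expression.tsv", "tsv")
tfs <- readLines("results/tf_list.txt")
subtype_sig <- read_gmt("results/subtype_signature.gmt")
labels <- read.delim("results/subtype_labels.tsv")
truth <- read.delim("results/truth_samples.tsv")

net <- infer_regulons(X, tfs, n_permutations = 100, bh_alpha = 0.01, seed = 3)
message(sprintf("raw network: %d edges", nrow(network_edges(net))))
net <- bootstrap_filter(X, net, n_bootstraps = 100, support_threshold = 0.95,
                        seed = 4)
message(sprintf("after bootstrap (support >= 0.95): %d edges",
                nrow(network_edges(net))))
net <- apply_dpi(net, epsilon = 0)
message(sprintf("after DPI: %d edges", nrow(network_edges(net))))
write_network(net, "results/network_edges.tsv")

# map clusters to subtype names through the planted truth, then test every
# regulon against the mesenchymal and immunoreactive up-signatures
core <- labels$sample_id[labels$core]
map <- vapply(split(truth$subtype[match(core, truth$sample_id)],
                    labels$cluster[labels$core]),
              function(z) names(which.max(table(z))), character(1))
reports <- list()
for (s in c("Mesenchymal", "Immunoreactive")) {
  sig <- subtype_sig[[paste0("subtype_", names(map)[map == s], "_up")]]
  res <- mra(net, sig)
  res$signature <- s
  reports[[s]] <- res
  message(sprintf("%s: %d TFs tested, %d master regulators: %s", s, nrow(res),
                  sum(res$is_master),
                  paste(res$tf[res$is_master], collapse = ", ")))
}
report <- do.call(rbind, reports)
write.table(report, "results/mra_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# GSEA validation of the top mesenchymal call on the subtype contrast
mese_cluster <- names(map)[map == "Mesenchymal"]
in_cluster <- labels$sample_id[labels$cluster == as.integer(mese_cluster)]
ranking <- rowMeans(X[, colnames(X) %in% in_cluster]) -
  rowMeans(X[, !colnames(X) %in% in_cluster])
top_tf <- reports$Mesenchymal$tf[1]
val <- gsea_validate_mr(net, top_tf, ranking, n_permutations = 1000, seed = 6)
message(sprintf("GSEA validation of %s: ES %.2f, q %.3g", top_tf, val$es,
                val$fdr_q))
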