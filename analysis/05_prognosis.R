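#!/usr/bin/env Rscript
# Prognostic stratification: MR compound scores, median dichotomization,
# the three-group stratification, pooled Kaplan-Meier / log-rank over two
# cohorts, the both-active contrast, and per-MR hazard ratios (forest data).

library(stromaMR)

X <- read_expression("results/expression.tsv", "tsv")
surv <- read_survival("results/survival.tsv", cohort_id = "synthetic")
sigs <- read_gmt("results/truth_signatures.gmt")

# a second, independent cohort from the same generator for the meta-analysis
co2 <- generate_cohort(cohort_config(seed = 2L))
X2 <- expression_matrix(unclass(co2$expression), dataset_id = "cohort2")
colnames(X2) <- paste0("c2_", colnames(X2))
sv2 <- co2$survival
sv2$cohort_id <- "cohort2"
sv2$sample_id <- paste0("c2_", sv2$sample_id)

ma <- meta_analyze(list(list(expression = X, survival = surv),
                        list(expression = X2, survival = sv2)),
                   sigs$mese_mrs, sigs$immu_mrs)
message(sprintf("pooled n = %d; group sizes: %s", nrow(ma$scores),
                paste(names(table(ma$scores$group)), table(ma$scores$group),
                      collapse = ", ")))
message(sprintf("median survival (months): %s",
                paste(names(ma$median_by_group),
                      round(ma$median_by_group, 1), collapse = ", ")))
message(sprintf("three-group log-rank: chi2 %.1f, p %.3g",
                ma$logrank$chi2, ma$logrank$p))
message(sprintf("immu+mese- vs immu+mese+ contrast: p %.3g", ma$contrast$p))

write.table(ma$scores, "results/prognostic_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
km_rows <- do.call(rbind, Map(function(g, km)
  if (!is.null(km)) cbind(group = g, km), names(ma$km), ma$km))
write.table(km_rows, "results/km_curves.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fr <- forest_table(X, surv, c(sigs$mese_mrs$members, sigs$immu_mrs$members))
fr$program <- ifelse(fr$gene %in% sigs$mese_mrs$members,
                     "mesenchymal", "immunoreactive")
message("per-MR hazard ratios (z-scored expression):")
print(fr, digits = 3)
write.table(fr, "results/forest_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
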