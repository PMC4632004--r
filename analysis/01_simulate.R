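#!/usr/bin/env Rscript
# Simulate the study cohort: 500 genes x 200 samples, four subtypes, 6 + 10
# planted stromal master regulators with 18-target regulons, per-sample
# stromal admixture, and exponential survival driven by the two planted
# program scores. Writes the expression matrix, ground truth and survival
# under results/.

library(stromaMR)

dir.create("results", showWarnings = FALSE)
cfg <- cohort_config(seed = 1L)
cohort <- generate_cohort(cfg)

write_expression(cohort$expression, "results/expression.tsv")
write_survival(cohort$survival, "results/survival.tsv")
write_gmt(list(cohort$mese_signature, cohort$immu_signature,
               cohort$mese_mrs, cohort$immu_mrs),
          "results/truth_signatures.gmt")
truth <- data.frame(sample_id = names(cohort$true_subtype),
                    subtype = cohort$true_subtype,
                    stromal_fraction = cohort$stromal_fraction)
write.table(truth, "results/truth_samples.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(cohort$tf_list, "results/tf_list.txt")

message(sprintf("cohort: %d genes x %d samples; subtype counts: %s",
                nrow(cohort$expression), ncol(cohort$expression),
                paste(names(table(cohort$true_subtype)),
                      table(cohort$true_subtype), collapse = ", ")))
message(sprintf("event rate %.2f, median follow-up %.1f months",
                mean(cohort$survival$event), median(cohort$survival$time)))
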