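#!/usr/bin/env Rscript
# Cis analyses of the prognosis lncRNAs: sense/antisense and locus-neighbour
# Spearman correlations per risk subgroup, the H19/IGF2 and H19/miR-675
# ratio-discordance calls against the healthy-control reference, and the
# log-rank comparison of concordant vs discordant patients.

library(lncmodnet)

outdir <- "results/concordance"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
study <- read_expression_study("results/study/expression.tsv",
                               "results/study/genes.tsv",
                               "results/study/samples.tsv")
truth_disc <- readLines("results/study/truth_discordant.txt")

ipss <- stratify_by_ipssr(study)
ctr_ids <- samples_in_groups(study, "CTR")
inter <- setdiff(study$samples$sample_id,
                 c(ctr_ids, ipss$lower, ipss$higher))
subgroups <- list(all = study$samples$sample_id,
                  ctr_and_lower = c(ctr_ids, ipss$lower),
                  inter_and_higher = c(inter, ipss$higher))

pairs <- list(c("WT1", "WT1-AS"), c("LEF1", "LEF1-AS1"),
              c("H19", "IGF2"), c("H19", "miR-675"), c("IGF2", "miR-675"))
cis <- cis_pair_correlation(study, pairs, subgroups)
write.table(cis, file.path(outdir, "cis_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("cis-pair Spearman correlations:\n")
print(cis, row.names = FALSE, digits = 3)

for (pair in list(c("H19", "IGF2"), c("H19", "miR-675"))) {
  nm <- paste(gsub("[^A-Za-z0-9]", "", pair), collapse = "_")
  calls <- classify_concordance(study, pair[1], pair[2], ctr_ids)
  write.table(calls, file.path(outdir, paste0("calls_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  disc <- calls$sample_id[calls$label == "discordant"]
  cat("\n", pair[1], "/", pair[2], ": ", length(disc),
      " discordant samples (", sum(disc %in% truth_disc),
      " of the planted ", length(truth_disc), " recovered)\n", sep = "")
  surv <- discordance_survival_test(study, calls)
  print(surv, row.names = FALSE, digits = 4)
  write.table(surv, file.path(outdir, paste0("survival_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
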