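#!/usr/bin/env Rscript
# Differential expression over the simulated cohort: MDS vs CTR and AML-MRC
# vs MDS at |logFC| > 1, mutation-carrier contrasts at the refined
# |logFC| > 0.3 threshold, the 18-month survival and IPSS-R risk contrasts,
# and the eight-group one-way ANOVA with 3-cluster group dendrogram.

library(lncmodnet)

outdir <- "results/de"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
study <- read_expression_study("results/study/expression.tsv",
                               "results/study/genes.tsv",
                               "results/study/samples.tsv")

run_contrast <- function(name, a, b, lfc = 1) {
  ctr <- contrast(name, a, b, lfc_threshold = lfc)
  de <- moderated_t_contrast(study, ctr)
  calls <- call_significant(de, ctr)
  write.table(de[order(de$q), ], file.path(outdir, paste0(name, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-18s lncRNA %3d up / %3d down; PCG %3d up / %3d down\n",
              name,
              calls$counts["lncRNA", "up"], calls$counts["lncRNA", "down"],
              calls$counts["PCG", "up"], calls$counts["PCG", "down"]))
  invisible(calls)
}

run_contrast("mds_vs_ctr", samples_in_groups(study, "MDS"),
             samples_in_groups(study, "CTR"))
run_contrast("aml_vs_mds", samples_in_groups(study, "AML-MRC"),
             samples_in_groups(study, "MDS"))

surv <- stratify_by_survival(study)
run_contrast("short_vs_long_os", surv$short, surv$long)
ipss <- stratify_by_ipssr(study)
run_contrast("higher_vs_lower_ipssr", ipss$higher, ipss$lower)

for (sym in c("SF3B1", "TET2", "TP53", "DNMT3A", "RUNX1")) {
  sets <- mutation_carrier_sets(study, sym)
  pat <- study$samples$sample_id[study$samples$group != "CTR"]
  run_contrast(paste0(tolower(sym), "_mut_vs_wt"),
               intersect(sets$mutated, pat), intersect(sets$wildtype, pat),
               lfc = 0.3)
}

an <- anova_profile(study)
cl <- cluster_groups(an, n_clusters = 3)
cat("ANOVA-significant genes (FDR < 0.05):", cl$n_significant, "\n")
cat("group clusters:\n")
print(cl$clusters)
write.table(an$table[order(an$table$q), ], file.path(outdir, "anova.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(group = names(cl$clusters), cluster = cl$clusters),
            file.path(outdir, "group_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
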