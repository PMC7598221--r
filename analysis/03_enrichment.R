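#!/usr/bin/env Rscript
# Permutation GSEA of the MDS vs CTR contrast against the simulated term
# collection; the module-matched terms should surface with positive NES.

library(lncmodnet)

outdir <- "results/gsea"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
study <- read_expression_study("results/study/expression.tsv",
                               "results/study/genes.tsv",
                               "results/study/samples.tsv")
sets <- read_gmt("results/study/terms.gmt")

ctr <- contrast("mds_vs_ctr", samples_in_groups(study, "MDS"),
                samples_in_groups(study, "CTR"))
res <- gsea_significance(study, ctr, sets, n_perm = 1000, seed = 7)
res <- res[order(res$p_perm), ]
write.table(res, file.path(outdir, "gsea_mds_vs_ctr.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("gene sets tested:", nrow(res), "\n")
# phenotype permutation keeps inter-gene correlation, so coexpressed (module)
# sets have wide permutation nulls; the conventional GSEA FDR cut is 0.25
sig <- res[!is.na(res$q) & res$q < 0.25, ]
cat("sets at FDR < 0.25:", nrow(sig), "\n")
cat("top of the ranking (module-matched terms should lead with NES > 0):\n")
print(head(res[, c("set", "size", "ES", "NES", "p_perm", "q")], 8),
      row.names = FALSE, digits = 3)
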