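#!/usr/bin/env Rscript
# Generate the synthetic discovery cohort used by every downstream driver:
# 2000 lncRNAs + 2000 PCGs over 77 CD34+ samples (9 CTR, 54 MDS across six
# WHO subtypes, 14 AML-MRC), with planted group effects, three coexpression
# modules, mutation carriers for the five recurrent genes, risk-graded locus
# anchors (H19, WT1-AS, LEF1-AS1, TCL6 and partners) and marker-driven
# survival. Writes the study TSVs, the term annotations and the ground truth.

library(lncmodnet)

outdir <- "results/study"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(n_lnc = 2000, n_pcg = 2000, seed = 20200901)
sim <- simulate_study(cfg)
study <- simulate_survival(sim$study, cfg)
ann <- simulate_annotation(sim$truth, cfg)

write_expression_study(study,
                       file.path(outdir, "expression.tsv"),
                       file.path(outdir, "genes.tsv"),
                       file.path(outdir, "samples.tsv"))
write_gmt(ann$gmt, file.path(outdir, "terms.gmt"))
write.table(ann$term_table, file.path(outdir, "term_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# persist the planted truth for the recovery checks in later drivers
truth_modules <- do.call(rbind, lapply(names(sim$truth$modules), function(m)
  data.frame(module = m, gene_id = sim$truth$modules[[m]])))
write.table(truth_modules, file.path(outdir, "truth_modules.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
de_truth <- do.call(rbind, lapply(names(sim$truth$de), function(g)
  cbind(group = g, sim$truth$de[[g]])))
write.table(de_truth, file.path(outdir, "truth_de.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sim$truth$discordant_samples,
           file.path(outdir, "truth_discordant.txt"))

print(study)
cat("screened patients:",
    sum(study$samples$screened & study$samples$group != "CTR"), "\n")
cat("planted DE genes per patient group:",
    paste(names(sim$truth$de), vapply(sim$truth$de, nrow, 0L)), "\n")
cat("planted discordant samples:",
    length(sim$truth$discordant_samples), "\n")
cat("study written under", outdir, "\n")
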