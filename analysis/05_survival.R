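#!/usr/bin/env Rscript
# Prognosis analyses: Kaplan-Meier curves for median-split lncRNA levels,
# log-rank tests, the univariate forest for OS and PFS, the Spearman
# covariate-correlation matrix, multivariate Cox with backward selection,
# and the IPSS-R < 4.5 lower/intermediate-risk sub-analysis.

library(lncmodnet)

outdir <- "results/survival"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
study <- read_expression_study("results/study/expression.tsv",
                               "results/study/genes.tsv",
                               "results/study/samples.tsv")

lncs <- c("H19", "WT1-AS", "LEF1-AS1", "TCL6")

# KM + log-rank for high vs low expression of each prognosis lncRNA
cat("log-rank tests on median-split expression (OS):\n")
for (g in lncs) {
  d <- dichotomize_expression(study, g)
  meta <- study$samples
  lo <- meta$sample_id %in% d$low & !is.na(meta$os_months)
  hi <- meta$sample_id %in% d$high & !is.na(meta$os_months)
  lr <- logrank_test(meta$os_months[lo], meta$os_event[lo],
                     meta$os_months[hi], meta$os_event[hi])
  cat(sprintf("  %-10s cut %6.2f  chi2 %6.2f  p %.4g\n",
              g, d$cutpoint, lr$chi2, lr$p))
  km_lo <- km_estimate(meta$os_months[lo], meta$os_event[lo])
  km_hi <- km_estimate(meta$os_months[hi], meta$os_event[hi])
  km <- rbind(cbind(stratum = "low", km_lo), cbind(stratum = "high", km_hi))
  write.table(km, file.path(outdir, paste0("km_", gsub("[^A-Za-z0-9]", "_", g),
                                           "_os.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# univariate forest over lncRNAs, clinical variables and TP53 mutation
vars <- c(lncs, "age", "blast_pct", "hemoglobin", "neutrophils", "platelets",
          "mut_TP53")
for (ep in c("os", "pfs")) {
  forest <- univariate_forest(study, vars, ep)
  write.table(forest, file.path(outdir, paste0("forest_", ep, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\nunivariate forest (", toupper(ep), "):\n", sep = "")
  print(forest, row.names = FALSE, digits = 3)
}

# pairwise Spearman correlations among the model covariates
sp <- spearman_matrix(study, vars)
write.table(round(sp$r, 3), file.path(outdir, "spearman_r.tsv"),
            sep = "\t", quote = FALSE)
write.table(signif(sp$p, 3), file.path(outdir, "spearman_p.tsv"),
            sep = "\t", quote = FALSE)

# multivariate Cox with backward selection, all patients then IPSS-R < 4.5
for (ep in c("os", "pfs")) {
  rec <- survival_records(study, ep, vars)
  sel <- backward_select(rec, vars)
  cat("\nbackward-selected model (", toupper(ep), ", all patients):\n",
      sep = "")
  print(sel$model)
  mt <- with(sel$model, data.frame(variable = variables, HR = HR,
                                   ci95_low = ci95_low, ci95_high = ci95_high,
                                   p = wald_p))
  write.table(mt, file.path(outdir, paste0("cox_", ep, "_all.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sel$removal_trace,
              file.path(outdir, paste0("cox_", ep, "_all_trace.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

low <- lower_risk_subanalysis(study, vars)
cat("\nlower/intermediate-risk sub-analysis on", low$n_selected, "patients\n")
for (ep in c("os", "pfs")) {
  cat("retained (", toupper(ep), "): ",
      paste(low[[ep]]$model$variables, collapse = ", "), "\n", sep = "")
  mt <- with(low[[ep]]$model, data.frame(variable = variables, HR = HR,
                                         ci95_low = ci95_low,
                                         ci95_high = ci95_high, p = wald_p))
  write.table(mt, file.path(outdir, paste0("cox_", ep, "_lower_risk.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
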