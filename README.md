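# lncmodnet

Joint lncRNA–protein-coding-gene (PCG) expression analysis for
myelodysplastic syndrome (MDS) CD34+ bone marrow profiling studies, built as
a reusable R package plus a numbered analysis workflow. It is aimed at
computational biologists who profile both transcript classes in one cohort
and want to go from a normalized log2 expression matrix to (i) deregulated
transcript lists, (ii) functionally annotated lncRNA–PCG coexpression
modules, and (iii) survival models that rank lncRNA levels against the
clinical variables used for MDS risk stratification.

## What it computes

- **Moderated-t differential expression.** Per gene,
  `logFC = x̄_A − x̄_B`, pooled residual variance `s²_g` on
  `d_g = n_A + n_B − 2` df, an empirical-Bayes variance prior `(d₀, s²₀)`
  fitted by the method of moments on `log s²_g` (digamma/trigamma closed
  forms), posterior variance
  `s²_post = (d₀ s²₀ + d_g s²_g) / (d₀ + d_g)`, and
  `t = logFC / √(s²_post (1/n_A + 1/n_B))` on `d₀ + d_g` df, with
  Benjamini–Hochberg FDR. Calls use strict `|logFC| > 1` (or the refined
  `0.3`) and `FDR < 0.05`. One-way ANOVA profiles the eight WHO-style groups
  and average-linkage clustering of group-mean logFC-vs-control vectors
  yields the 3-cluster group structure.
- **Permutation GSEA.** Weighted Kolmogorov–Smirnov running sum
  (hits add `|r|^p / Σ_hits |r|^p`, misses subtract `1/(N−N_H)`), ES at the
  extremum, `NES = ES / mean |permuted ES of the same sign|`, phenotype-label
  permutations (gene-set permutation fallback below 7 samples per group).
- **NMF coexpression modules.** Pearson correlation matrix over the DE
  transcripts, clipped at zero (`A = max(C, 0)`) so modules collect
  similarly regulated genes, factorized as `A ≈ WH` by multiplicative
  updates minimizing `‖A − WH‖²_F` with random restarts; the rank is chosen
  by consensus-clustering cophenetic correlation. Genes go to their argmax
  module of the column-normalized `(W + Hᵀ)/2`; each module reports cores of
  up to 4 lncRNAs and 13 PCGs with the highest membership, and is annotated
  by upper-tail hypergeometric enrichment of its PCG members
  (guilt-by-association for the lncRNAs). An lncRNA-centred variant builds
  the network from focus lncRNAs plus their top-correlated DE PCGs.
- **Survival.** Kaplan–Meier product limit, two-group log-rank
  (O−E with hypergeometric variance), Cox proportional hazards maximizing
  the Efron-ties partial likelihood by Newton–Raphson, Wald
  `exp(β ± 1.96 se)` intervals, backward elimination at `p > 0.05`,
  univariate forest tables, Spearman covariate matrices, 18-month OS
  stratification, and the IPSS-R `< 4.5` lower/intermediate-risk
  sub-analysis.
- **Ratio discordance.** For an imprinted locus pair `(x, y)` the
  linear-scale ratio `2^(x−y)` is compared to the healthy-control median;
  a per-sample fold change `> 10` or `< 0.1` (strict) labels the sample
  discordant, and concordant vs discordant survival is compared by log-rank.
- **Synthetic cohorts.** `simulate_study()` generates studies from
  `x_gs = μ_g + Σ_c δ_gc·1[s∈c] + Σ_m λ_gm f_ms + ε_gs` with planted DE
  genes, coexpression modules, mutation carriers (5% VAF convention),
  risk-graded locus anchors (H19, WT1-AS, LEF1-AS1, TCL6 and partners) and
  exponential survival driven by marker expression — every downstream stage
  has a recovery-based test against this ground truth.

## Worked example

```r
library(lncmodnet)

cfg   <- simulation_config(n_lnc = 500, n_pcg = 500, seed = 42)
sim   <- simulate_study(cfg)
study <- simulate_survival(sim$study, cfg)

ctr <- contrast("mds_vs_ctr", samples_in_groups(study, "MDS"),
                samples_in_groups(study, "CTR"))
de  <- moderated_t_contrast(study, ctr)
call_significant(de, ctr)$counts
#>         direction
#> biotype   up down  ns
#>   lncRNA  46    0 454
#>   PCG    120    0 380

de_ids <- de$gene_id[de$q < 0.05 & abs(de$logFC) > 1]
net <- coexpression_modules(study, de_ids, k = 3, seed = 1)
sapply(net$modules, function(m) nrow(m$members))
#> M1 M2 M3
#> 55 56 55        # the three planted 55-gene modules, recovered

rec <- survival_records(study, "os", c("H19", "blast_pct", "age", "mut_TP53"))
backward_select(rec, c("H19", "blast_pct", "age", "mut_TP53"))$model
#> CoxModel on 64 records / 42 events
#>  variable    HR        ci95        p
#>       H19 2.402 1.581-3.648 3.97e-05
```

The DE table recovers the planted disease-wide effects (all up-shifted, so
no down calls at this seed); the NMF pipeline returns the three planted
modules intact; and backward selection keeps only H19 — the simulated
hazard marker (log-hazard 0.7 per SD of expression) — discarding the null
clinical covariates.

The full cohort walkthrough lives in `analysis/01_simulate.R` …
`analysis/06_concordance.R`; each driver prints what it found and writes
its tables under `results/`.

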