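---
title: "Methods: lncRNA-PCG coexpression modules, differential expression and survival modelling"
author: "lncmodnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA-PCG coexpression modules, differential expression and survival modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmodnet)
```

# Scope and data model

lncmodnet analyses joint lncRNA/PCG expression profiles of CD34+ bone
marrow cells across an MDS disease spectrum. The universal container is the
`ExpressionStudy`: a genes x samples matrix of normalized log2 intensities,
a gene annotation (unique `gene_id`, biotype in {lncRNA, PCG, miRNA},
optional sense/antisense or locus `partner_id`), and per-sample metadata
(WHO-style group, IPSS-R score and category, karyotype, mutation map of
gene symbol to VAF fraction, OS/PFS endpoints, blood counts). Expression is
consumed on the log2 scale throughout; only the concordance classifier
moves to the linear scale via `2^x`. Input order of genes and samples is
preserved everywhere - no silent sorting - and missing clinical fields stay
missing: analyses are complete-case, with the number of dropped patients
reported, never imputed.

Three cohort stratifiers feed the contrasts. The overall-survival split at
18 months counts a death at exactly 18 months as short survival; patients
censored at or before the cut-off carry no information about which side
they belong to and are excluded (this exclusion is a documented choice -
an alternative would be assigning censored patients to the long-survival
arm, which biases toward optimism). The IPSS-R split pools {very low, low}
against {high, very high} and excludes intermediate-risk MDS, AML-MRC and
controls. Mutation carriers are samples with any variant above 5% VAF -
strictly above, so a VAF of exactly 0.05 is wild type - and unscreened
samples (no mutation record) are left out of both arms.

# Differential expression

For a two-group contrast the per-gene statistic is a moderated t. With
pooled residual variance $s^2_g$ on $d_g = n_A + n_B - 2$ df, the variance
prior $(d_0, s^2_0)$ is fitted by the method of moments on
$z_g = \log s^2_g$: since $z_g$ is a log scaled chi-square,
$e_g = z_g - \psi(d_g/2) + \log(d_g/2)$ has mean
$\log s^2_0 - \psi(d_0/2) + \log(d_0/2)$ and excess variance
$\psi'(d_0/2)$, so $d_0$ comes from inverting the trigamma function
(Newton iteration) on the excess spread of $e_g$. When the observed spread
does not exceed the sampling noise the prior is fully pooled
($d_0 = \infty$) and the posterior variance is the arithmetic mean of the
$s^2_g$ - the maximum-likelihood variance under a single shared scale; the
moderated statistic is then referred to the normal distribution. A
single-gene matrix falls back to the ordinary pooled t with a warning.
The construction is cross-checked against limma's `lmFit`/`eBayes` in the
test suite (agreement of prior df, prior variance, t and p to 1e-8 on a
fixture with heterogeneous gene variances).

Multiple testing uses Benjamini-Hochberg step-up (delegated to
`stats::p.adjust`; the direct step-up formula serves as the independent
oracle in tests). Significance calls are strict at both thresholds:
`|logFC| > 1` by default, the refined `0.3` variant for mutation contrasts
where effects are subtler, always with `FDR < 0.05`.

The eight-group comparison uses the classical one-way F per gene,
vectorized over the matrix, with BH across genes. Group clustering runs
average-linkage hierarchical clustering on Euclidean distances between the
group-mean logFC-versus-control vectors restricted to ANOVA-significant
genes, cut to three flat clusters by default. Clustering group means (not
individual samples) matches the eight-column heatmap layout this display
emulates; the alternative - clustering samples - answers a different
question and is not provided.

# Enrichment

The GSEA enrichment score walks the ranked gene list (moderated t by
default; the ranking metric is configurable since phenotype-correlation
metrics are interchangeable here), adding $|r_j|^p / \sum_{hits} |r|^p$ at
set members and subtracting $1/(N - N_H)$ otherwise; the ES is the
running-sum extremum of largest magnitude and `weight_p = 0` reduces to the
classical Kolmogorov-Smirnov statistic. Significance uses phenotype-label
permutation - preserving inter-gene correlation, which matters for
coexpressed sets - with NES defined as ES over the mean |permuted ES| of
the same sign and a one-sided permutation p within sign. Below 7 samples in
either group the label space is too small and the implementation falls back
to gene-set (ranking-position) permutation with a warning. FDR is computed
by BH within each sign pool of the permutation p-values; this is simpler
than the original permuted-NES ratio estimator and slightly conservative
for coexpressed sets.

Module annotation is upper-tail hypergeometric: population = the DE PCGs in
the network, draws = a module's PCG members, reported at raw p < 0.01
(matching the convention of the guilt-by-association table this emulates),
with BH q-values emitted alongside for transparency.

# Coexpression modules by NMF

The network is built over differentially expressed transcripts only
(FDR < 0.05), correlating each pair across the contrast's sample union with
Pearson correlation by default (Spearman available; the choice is exposed
because rank correlation trades power for outlier robustness). Exact
symmetry is enforced by averaging with the transpose; zero-variance genes
are dropped with a warning.

The correlation matrix is mapped to a nonnegative matrix before
factorization. The default is positive clipping `A = max(C, 0)`: modules
are meant to collect *similarly regulated* genes, and absolute values would
conflate anti-correlation with co-regulation. `abs` and `shift`
(`(C+1)/2`) remain as sensitivity options since the choice cannot be
recovered from the published description.

Factorization minimizes $\|A - WH\|_F^2$ by the classical multiplicative
updates from uniform random starts on `[0.1, 1]`, keeping the best of
`n_restarts` (default 30) runs; a run converges when the relative objective
decrease falls below `tol` (default 1e-6, cap 2000 iterations). The
objective is non-increasing at every iteration - asserted per iteration in
the tests. The machine epsilon added to update denominators prevents
division by zero without affecting the monotonicity property in practice.

The rank is selected by consensus clustering: for each candidate k, the
co-assignment (argmax membership) indicator is averaged over restarts and
the consensus matrix is scored by the cophenetic correlation of its
average-linkage dendrogram; the k maximizing it wins, and a maximum below
0.9 sets a low-confidence flag (pure-noise matrices produce flat or
declining profiles). A fixed k can always be passed instead.

Membership is the column-normalized (unit Euclidean norm per module)
symmetrized factor $(W + H^\top)/2$ - for symmetric input W and H are
near-transposes, and symmetrizing removes the arbitrary asymmetry of the
update sequence. Genes go to their argmax module, ties to the lowest module
index; cores are the top 4 lncRNAs and top 13 PCGs per module by
membership, ties broken by lexicographic gene id. Deterministic builds
matter more than any particular tie convention.

The lncRNA-centred variant seeds the matrix with focus lncRNAs plus each
focus's top-q DE PCGs by absolute correlation (default q = 50) and returns
only the modules containing a focus, reporting which foci co-occupy a
module.

# Survival modelling

Kaplan-Meier, log-rank and Cox regression are implemented in the package
and validated against the survival package on fixtures (log-rank chi-square
and Cox coefficients to 1e-4 or better). The Cox fit maximizes the
Efron-tie partial likelihood by Newton-Raphson from zero, converging when
the largest score component drops below 1e-8 (cap 50 iterations); Efron's
approximation is the less biased tie handling and the modern default. Wald
intervals are $\exp(\beta \pm 1.96\,se)$. Monotone likelihood (separation,
e.g. a rare mutation flag whose carriers all relapse early) is detected by
a runaway coefficient and raised as an error naming the variable.

Backward elimination drops the variable with the largest Wald p above
`alpha_stay = 0.05` and refits until all remaining p <= 0.05; p-ties drop
the later input position first, and a separating variable is eliminated
with `p = NA` recorded in the trace - the standard practical resolution,
and the behavior needed for the lower-risk sub-analysis where mutation
flags can lose all their events. The final model is reported sorted by
descending p. `alpha_stay` is a convention; the source analyses say only
"significantly contributing".

Univariate screening mirrors the forest-plot convention: each variable is
assessed alone, with a one-covariate Cox fit on the continuous
(expression-standardized) value for the hazard ratio and a log-rank test on
the median-dichotomized variable for the starred p. Multivariate models
enter expression continuously, z-scored over the included patients - whether
the original Table entered levels continuously or binarized is not
recoverable, so both forms are exposed. Median split (ties low) is the
dichotomization default; a maximally selected log-rank cutpoint bounded to
the 10-90% quantiles is available but inflates type-I error if its p is
taken at face value.

# Concordance at the H19/IGF2 locus

The per-sample linear ratio $2^{x-y}$ is referenced to the median ratio of
healthy controls - the baseline is ambiguous in the source description, and
the control median is the natural anchor for "change"; a cohort-median
reference is configurable. A fold change of the ratio beyond 10 in either
direction (strictly; the two-sided reading of "> 10-fold change") labels
the sample discordant. Labels are symmetric in the pair and invariant to
adding a constant to both log2 profiles, both asserted as properties.

# The synthetic-data generator

`simulate_study()` draws
$x_{gs} = \mu_g + \sum_c \delta_{gc}\,1[s \in c] + \sum_m \lambda_{gm} f_{ms} + \varepsilon_{gs}$
with $\mu_g \sim N(7, 1.5^2)$ log2 units, module factor scores
$f_{ms} \sim N(0, \texttt{module\_factor\_sd}^2)$, unit loadings on module
members, and residual noise $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$.
Defaults are fixed to the discovery-cohort design this package emulates:
77 samples (9 controls, 54 MDS across six WHO subtypes - 6 SLD, 12 MLD,
8 RS, 8 del(5q), 10 EB1, 10 EB2 - and 14 AML-MRC), 10^4 lncRNA + 10^4 PCG
features, planted |logFC| of 2 for group effects with residual SD 0.5 log2
units (typical microarray scales), and 64 screened patients carrying
SF3B1/TET2/TP53/DNMT3A/RUNX1 mutations at the published counts
(14/10/10/9/9) with VAF drawn uniformly on [0.1, 0.5]. Mutation effects are
group-indicator expression shifts in carriers, mirroring how carrier
contrasts are analysed. Eight anchor genes (H19, WT1-AS, LEF1-AS1, TCL6;
IGF2, WT1, LEF1; miR-675) receive severity-graded effects (H19 and WT1-AS
up, LEF1-AS1/TCL6/IGF2/miR-675 down along a 0-1 disease-severity scale),
shared per-pair latent factors that induce the cis correlations, and a
configurable fraction (default 25%) of advanced-disease patients whose H19
is shifted by +4.5 log2 units - breaking the H19/IGF2/miR-675 coregulation
exactly as the discordance classifier expects, and coupling discordance to
hazard through H19's survival effect rather than by fiat.

Survival times are exponential with rate
$\lambda_0 \exp(\sum_g \beta_g z_{gs})$, $z$ the standardized marker
expression ($\beta_{H19} = 0.7$ per SD, $\lambda_0 = 0.03$/month by
default, median OS near two years); censoring is independent uniform on
$(0, c_{max})$ with $c_{max}$ solved numerically so the expected censored
fraction matches `censor_rate` (default 0.3). The constant baseline hazard
was chosen for closed-form sanity checks; PFS reuses the linear predictor
at 1.4x rate truncated at the OS time, a simplification of progression.
Annotation terms cover `term_enrichment` (default 0.8) of each planted
module plus uniform background sets of 10-50 genes.

What the generator does *not* emulate: probe-level array chemistry, batch
or array-washing effects, heavy-tailed or intensity-dependent noise,
correlated mutation co-occurrence, and non-proportional hazards. Passing
recovery tests therefore demonstrates algorithmic correctness under the
stated generative model, not robustness to those real-data pathologies.

# Problem sizes and calibration checks

The test suite and the acceptance script run deliberately scaled problems,
chosen as the package's own verification design: 50 null replicates of 200
genes at n = 10 + 10 for the moderated-t type-I error (nominal 0.05); 200
random 15-gene sets at 500 permutations for GSEA p uniformity; 500
null-and-signal simulations at n = 60 for Cox 95% CI coverage; 20
replicates of the full NMF pipeline on 3 planted modules (15 lncRNAs + 40
PCGs each, unit loadings, noise SD 0.3, 60 samples) scoring adjusted Rand
index against the plant; 100 replicates of hazard recovery
($\beta = 0.7$, 500 patients, 20% censoring); and 20 replicates of backward
selection with one planted marker and three null covariates at n = 400.

# Known limitations

- Backward selection with `alpha_stay = 0.05` and three pure-noise
  covariates succeeds (marker kept, all noise dropped) in about
  $0.95^3 \approx 86\%$ of replicates by construction - each noise
  covariate independently survives with roughly alpha probability - so
  seed-to-seed success rates fluctuate around that value rather than above
  90%.
- Phenotype-permutation GSEA on strongly coexpressed sets has a wide null:
  planted module terms can carry near-maximal ES yet only modest
  permutation p, which is statistically honest but means small collections
  may need the conventional 0.25 FDR threshold rather than 0.05.
- The NMF objective is non-convex; restarts mitigate but do not guarantee
  the global optimum, and the consensus rank selection can over-merge when
  module factor variance is far below the noise floor.
- With few controls (9 in the emulated design) the permutation label space
  for phenotype GSEA is limited, and the reference ratio of the concordance
  classifier rests on a 9-sample median.
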