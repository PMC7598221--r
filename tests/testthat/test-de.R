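test_that("detection filter keeps and drops the right genes", {
  study <- make_small_study(n_lnc = 2, n_pcg = 2, n_samples = 4, seed = 2)
  # min_fraction = 0 keeps everything regardless of signal
  same <- suppressMessages(detection_filter(study, min_signal = 100,
                                            min_fraction = 0))
  expect_identical(same$genes$gene_id, study$genes$gene_id)
  # a floor-valued gene is removed when the floor sits below min_signal
  study$matrix["LNC01", ] <- 2
  filt <- suppressMessages(detection_filter(study, min_signal = 3,
                                            min_fraction = 0.5))
  expect_false("LNC01" %in% filt$genes$gene_id)
  expect_error(suppressMessages(detection_filter(study, min_signal = 1e6,
                                                 min_fraction = 0.5)),
               "every gene")
})

test_that("detection filter bookkeeping matches a planted fixture", {
  set.seed(7)
  mat <- rbind(matrix(rnorm(70 * 6, 8, 0.5), 70, 6),
               matrix(rnorm(30 * 6, 2, 0.1), 30, 6))
  rownames(mat) <- sprintf("G%03d", 1:100)
  colnames(mat) <- sprintf("S%d", 1:6)
  genes <- data.frame(gene_id = rownames(mat), biotype = "PCG",
                      partner_id = NA_character_)
  samples <- data.frame(sample_id = colnames(mat),
                        group = rep(c("CTR", "MDS-MLD"), 3))
  study <- expression_study(mat, genes, samples)
  filt <- suppressMessages(detection_filter(study, min_signal = 5,
                                            min_fraction = 0.5))
  expect_equal(nrow(filt$matrix), 70)
})

test_that("duplicate probes collapse to the per-sample median", {
  mat <- matrix(c(4, 6, 1, 10, 20, 2), nrow = 3,
                dimnames = list(NULL, c("S1", "S2")))
  out <- collapse_duplicates(mat, c("GA", "GA", "GB"))
  expect_equal(out["GA", ], c(S1 = 5, S2 = 15))
  expect_equal(out["GB", ], c(S1 = 1, S2 = 2))
  # no duplicates: identity up to rownames
  out2 <- collapse_duplicates(mat, c("G1", "G2", "G3"))
  expect_equal(unname(out2), unname(mat))
  # 3 genes x {1,2,3} probes -> 3 rows
  mat3 <- matrix(seq_len(12), nrow = 6, dimnames = list(NULL, c("S1", "S2")))
  out3 <- collapse_duplicates(mat3, c("A", "B", "B", "C", "C", "C"))
  expect_equal(nrow(out3), 3)
  expect_equal(out3["C", "S1"], 5)
})

test_that("BH matches the hand-evaluated step-up formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(0.05, 10)), rep(0.05, 10))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance + agreement with the direct step-up oracle
  set.seed(13)
  p <- runif(50)
  q <- benjamini_hochberg(p)
  expect_equal(q, bh_stepup(p))
  perm <- sample(50)
  expect_equal(benjamini_hochberg(p[perm]), q[perm])
})

test_that("moderated t reduces to shared variance under identical s2", {
  # all genes share s2: shrinkage is a fixed point, any prior df
  mat <- rbind(c(0, 2, 0, 2, 1, 3, 1, 3),
               c(5, 7, 5, 7, 9, 11, 9, 11),
               c(1, 3, 1, 3, 0, 2, 0, 2)) + 0
  rownames(mat) <- c("G1", "G2", "G3")
  colnames(mat) <- sprintf("S%d", 1:8)
  genes <- data.frame(gene_id = rownames(mat), biotype = "PCG",
                      partner_id = NA_character_)
  samples <- data.frame(sample_id = colnames(mat),
                        group = rep(c("MDS-MLD", "CTR"), each = 4))
  study <- expression_study(mat, genes, samples)
  ctr <- contrast("t", sprintf("S%d", 1:4), sprintf("S%d", 5:8))
  de <- moderated_t_contrast(study, ctr)
  expect_equal(de$s2_post, de$s2_g, tolerance = 1e-8)
})

test_that("moderated t agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  study <- make_small_study(n_lnc = 40, n_pcg = 60, n_samples = 12,
                            groups = rep(c("MDS-MLD", "CTR"), each = 6),
                            seed = 99)
  # heterogeneous gene variances so the prior df are finite and shrinkage real
  set.seed(100)
  gene_sd <- sqrt(1 / rgamma(100, shape = 4, rate = 4))
  study$matrix <- 7 + study$matrix * 0 +
    matrix(rnorm(100 * 12), 100, 12) * gene_sd
  study$matrix[1:10, 1:6] <- study$matrix[1:10, 1:6] + 1.5
  ctr <- contrast("t", sprintf("S%02d", 1:6), sprintf("S%02d", 7:12))
  de <- moderated_t_contrast(study, ctr)
  design <- cbind(1, rep(c(1, 0), each = 6))
  fit <- limma::eBayes(limma::lmFit(study$matrix, design))
  expect_true(is.finite(de$d0[1]))
  expect_equal(de$d0[1], fit$df.prior, tolerance = 1e-6)
  expect_equal(de$s2_0[1], fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("swapping contrast groups negates logFC and preserves p", {
  study <- make_small_study(n_lnc = 10, n_pcg = 10, n_samples = 10,
                            groups = rep(c("MDS-MLD", "CTR"), each = 5),
                            seed = 3)
  a <- sprintf("S%02d", 1:5); b <- sprintf("S%02d", 6:10)
  de_ab <- moderated_t_contrast(study, contrast("ab", a, b))
  de_ba <- moderated_t_contrast(study, contrast("ba", b, a))
  expect_equal(de_ab$logFC, -de_ba$logFC)
  expect_equal(de_ab$p, de_ba$p)
})

test_that("significance calls use strict thresholds and split by biotype", {
  res <- data.frame(gene_id = c("L1", "L2", "P1", "P2"),
                    biotype = c("lncRNA", "lncRNA", "PCG", "PCG"),
                    logFC = c(1.0, 2.0, -2.0, 0.5),
                    q = c(0.001, 0.001, 0.001, 0.001))
  ctr <- contrast("x", c("a", "b"), c("c", "d"))
  calls <- call_significant(res, ctr)
  expect_false("L1" %in% c(calls$up, calls$down))  # logFC exactly at threshold
  expect_identical(calls$up, "L2")
  expect_identical(calls$down, "P1")
  expect_equal(as.integer(calls$counts["lncRNA", "up"]), 1L)
  # a lower threshold can only add calls
  ctr03 <- contrast("x", c("a", "b"), c("c", "d"), lfc_threshold = 0.3)
  calls03 <- call_significant(res, ctr03)
  expect_true(all(c(calls$up, calls$down) %in% c(calls03$up, calls03$down)))
  expect_gt(length(calls03$up) + length(calls03$down),
            length(calls$up) + length(calls$down))
})

test_that("planted up/down genes are recovered at high power", {
  cfg <- simulation_config(n_lnc = 100, n_pcg = 100, n_modules = 1,
                           module_size_lnc = 1, module_size_pcg = 1,
                           module_factor_sd = 1e-6, de_fraction = 0.15,
                           de_logfc = 2, noise_sd = 0.2,
                           n_samples_per_group = c("CTR" = 20, "MDS-MLD" = 20),
                           mutation_carriers = c(), mutation_de_genes = 0,
                           include_anchors = FALSE,
                           n_unscreened_patients = 0,
                           n_unscreened_controls = 0, seed = 77)
  sim <- simulate_study(cfg)
  ctr <- contrast("mds", samples_in_groups(sim$study, "MDS-MLD"),
                  samples_in_groups(sim$study, "CTR"))
  de <- moderated_t_contrast(sim$study, ctr)
  calls <- call_significant(de, ctr)
  truth <- sim$truth$de$`MDS-MLD`
  planted_up <- truth$gene_id[truth$logfc > 0]
  planted_dn <- truth$gene_id[truth$logfc < 0]
  hits <- sum(calls$up %in% planted_up) + sum(calls$down %in% planted_dn)
  expect_gte(hits / nrow(truth), 0.9)
  false_calls <- sum(!c(calls$up, calls$down) %in% truth$gene_id)
  expect_lte(false_calls / max(1, length(c(calls$up, calls$down))), 0.1)
})

test_that("one-way ANOVA reduces to the pooled t with two groups", {
  study <- make_small_study(n_lnc = 5, n_pcg = 5, n_samples = 10,
                            groups = rep(c("CTR", "MDS-MLD"), each = 5),
                            seed = 8)
  an <- anova_profile(study)
  ctr <- contrast("x", sprintf("S%02d", 6:10), sprintf("S%02d", 1:5))
  a <- study$matrix[, 6:10]; b <- study$matrix[, 1:5]
  s2 <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) / 8
  t_ord <- (rowMeans(a) - rowMeans(b)) / sqrt(s2 * (2 / 5))
  expect_equal(an$table$F, unname(t_ord^2), tolerance = 1e-10)
  expect_equal(an$logfc_vs_ctr[, "CTR"], rep(0, 10), ignore_attr = TRUE)
})

test_that("ANOVA matches aov on a spot-checked gene and finds planted gradients", {
  study <- make_small_study(n_lnc = 10, n_pcg = 10, n_samples = 30,
                            groups = rep(c("CTR", "MDS-MLD", "MDS-EB2"), each = 10),
                            seed = 12)
  grad <- rep(c(0, 1.5, 3), each = 10)
  study$matrix["LNC01", ] <- 7 + grad + rnorm(30, 0, 0.4)
  an <- anova_profile(study)
  g <- factor(study$samples$group)
  ref <- summary(stats::aov(study$matrix["LNC05", ] ~ g))[[1]]
  expect_equal(an$table$F[an$table$gene_id == "LNC05"],
               ref$`F value`[1], tolerance = 1e-8)
  expect_lt(an$table$q[an$table$gene_id == "LNC01"], 0.05)
})

test_that("group clustering recovers planted profile structure", {
  set.seed(5)
  n_genes <- 40
  centers <- list(A = 0, B = 3, C = -3)
  groups <- c("CTR", "MDS-SLD", "MDS-MLD", "MDS-RS", "MDS-EB2", "AML-MRC")
  plan <- c(CTR = "A", `MDS-SLD` = "A", `MDS-MLD` = "B", `MDS-RS` = "B",
            `MDS-EB2` = "C", `AML-MRC` = "C")
  mat <- do.call(cbind, lapply(rep(groups, each = 4), function(g)
    rnorm(n_genes, 7 + centers[[plan[g]]], 0.3)))
  colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  rownames(mat) <- sprintf("G%02d", seq_len(n_genes))
  genes <- data.frame(gene_id = rownames(mat), biotype = "lncRNA",
                      partner_id = NA_character_)
  samples <- data.frame(sample_id = colnames(mat), group = rep(groups, each = 4))
  study <- expression_study(mat, genes, samples)
  an <- anova_profile(study)
  cl <- cluster_groups(an, n_clusters = 3)
  expect_equal(ari(cl$clusters[names(plan)], plan), 1)
  # groups with identical planted profiles merge far below the planted
  # between-profile separation (~sqrt(n_genes) * 3)
  merge_h <- cl$hclust$height[1]
  expect_lt(merge_h, 0.2 * max(cl$hclust$height))
  # as many clusters as groups yields singletons
  cl_all <- cluster_groups(an, n_clusters = length(groups))
  expect_equal(sort(unique(cl_all$clusters)), seq_along(groups))
  expect_true(all(table(cl_all$clusters) == 1))
})
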