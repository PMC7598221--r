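block_correlation <- function(sizes, within = 0.8, between = -0.3) {
  n <- sum(sizes)
  c_mat <- matrix(between, n, n)
  off <- 0
  for (s in sizes) {
    c_mat[off + seq_len(s), off + seq_len(s)] <- within
    off <- off + s
  }
  diag(c_mat) <- 1
  rownames(c_mat) <- colnames(c_mat) <- sprintf("G%03d", seq_len(n))
  c_mat
}

test_that("correlation matrix matches the textbook formula and is symmetric", {
  study <- make_small_study(n_lnc = 3, n_pcg = 2, n_samples = 8, seed = 31)
  ids <- study$genes$gene_id
  cm <- build_correlation_matrix(study, ids)
  expect_equal(diag(cm$C), rep(1, 5), ignore_attr = TRUE)
  expect_equal(cm$C, t(cm$C), tolerance = 1e-9)
  x <- study$matrix[1, ]; y <- study$matrix[4, ]
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm$C[1, 4], manual, tolerance = 1e-12)
  # perfectly anti-correlated pair
  study$matrix[2, ] <- -study$matrix[1, ]
  cm2 <- build_correlation_matrix(study, ids)
  expect_equal(cm2$C[1, 2], -1)
  # zero-variance gene is dropped with a warning
  study$matrix[3, ] <- 5
  expect_warning(cm3 <- build_correlation_matrix(study, ids), "zero-variance")
  expect_false(ids[3] %in% cm3$gene_ids)
})

test_that("nonnegative transforms follow their definitions", {
  c_mat <- matrix(c(1, -0.8, -0.8, 1), 2, 2)
  expect_equal(nonnegative_transform(c_mat, "positive_clip")[1, 2], 0)
  expect_equal(nonnegative_transform(c_mat, "abs")[1, 2], 0.8)
  expect_equal(nonnegative_transform(c_mat, "shift")[1, 2], 0.1)
  pos <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_equal(nonnegative_transform(pos, "positive_clip"), pos)
  blocks <- block_correlation(c(3, 3), within = 0.8, between = -0.3)
  a <- nonnegative_transform(blocks, "positive_clip")
  expect_true(all(a[1:3, 4:6] == 0))
  expect_true(all(a[1:3, 1:3] > 0))
})

test_that("NMF reconstructs exact low-rank structure", {
  # rank-1: outer product of a nonnegative vector
  v <- c(1, 2, 0.5, 3)
  a1 <- outer(v, v)
  fit1 <- nmf_factorize(a1, k = 1, n_restarts = 3, seed = 2)
  expect_lt(sum((a1 - fit1$W %*% fit1$H)^2), 1e-6)
  # exact rank-3 block-diagonal matrix (constant blocks, one per factor)
  blocks <- kronecker(diag(3), matrix(0.8, 5, 5))
  fit <- nmf_factorize(blocks, k = 3, n_restarts = 10, seed = 3)
  rel_err <- fit$objective / sum(blocks^2)
  expect_lt(rel_err, 1e-3)
  expect_error(nmf_factorize(blocks, k = 20), "below the matrix dimension")
})

test_that("the NMF objective never increases across iterations", {
  set.seed(17)
  a <- matrix(runif(30 * 30), 30, 30)
  a <- (a + t(a)) / 2
  fit <- nmf_factorize(a, k = 4, n_restarts = 3, max_iter = 300, seed = 5,
                       record_objective = TRUE)
  expect_true(all(diff(fit$trace) <= 1e-10))
})

test_that("consensus cophenetic rank selection finds planted blocks", {
  blocks <- nonnegative_transform(
    block_correlation(c(8, 8, 8), within = 0.8, between = -0.3),
    "positive_clip")
  sel <- select_rank(blocks, k_range = 2:5, n_restarts = 8, seed = 6)
  expect_equal(sel$k, 3)
  expect_false(sel$low_confidence)
  sel2 <- select_rank(blocks, k_range = 2:5, n_restarts = 8, seed = 6)
  expect_identical(sel, sel2)
})

test_that("module assignment caps cores and respects ties deterministically", {
  # 2 lncRNAs + 5 PCGs in one clean module: caps not binding, all are core
  blocks <- nonnegative_transform(
    block_correlation(c(7, 4), within = 0.9, between = 0), "positive_clip")
  ids <- rownames(blocks)
  bts <- c(rep("lncRNA", 2), rep("PCG", 5), rep("lncRNA", 4))
  fit <- nmf_factorize(blocks, k = 2, n_restarts = 10, seed = 7)
  mods <- assign_modules(fit$W, fit$H, ids, bts)
  big <- mods[[which.max(vapply(mods, function(m) nrow(m$members), 0))]]
  expect_setequal(big$members$gene_id, ids[1:7])
  expect_setequal(big$core_lncRNAs, ids[1:2])
  expect_setequal(big$core_PCGs, ids[3:7])
  # memberships are sorted descending
  expect_true(all(diff(big$members$membership) <= 0))
  # core caps bind on a larger module
  mods_cap <- assign_modules(fit$W, fit$H, ids, rep("PCG", 11), core_pcg = 3)
  expect_lte(length(mods_cap[[1]]$core_PCGs), 3)
})

test_that("module assignment is invariant to gene order up to relabeling", {
  blocks <- nonnegative_transform(
    block_correlation(c(6, 6), within = 0.8, between = -0.2), "positive_clip")
  ids <- rownames(blocks)
  fit <- nmf_factorize(blocks, k = 2, n_restarts = 5, seed = 8)
  mods <- assign_modules(fit$W, fit$H, ids, rep("PCG", 12))
  perm <- c(7:12, 1:6)
  fit_p <- nmf_factorize(blocks[perm, perm], k = 2, n_restarts = 5, seed = 8)
  mods_p <- assign_modules(fit_p$W, fit_p$H, ids[perm], rep("PCG", 12))
  part <- function(mods) {
    lab <- unlist(unname(lapply(mods, function(m)
      setNames(rep(m$module_id, nrow(m$members)), m$members$gene_id))))
    lab[ids]
  }
  expect_equal(ari(part(mods), part(mods_p)), 1)
})

test_that("planted modules are recovered end to end with high agreement", {
  cfg <- simulation_config(n_lnc = 45, n_pcg = 120, n_modules = 3,
                           module_size_lnc = 15, module_size_pcg = 40,
                           module_factor_sd = 1, de_fraction = 0, de_logfc = 0,
                           noise_sd = 0.3,
                           n_samples_per_group = c("CTR" = 10, "MDS-MLD" = 25,
                                                   "MDS-EB2" = 25),
                           mutation_carriers = c(), mutation_de_genes = 0,
                           include_anchors = FALSE, n_unscreened_patients = 0,
                           n_unscreened_controls = 0, seed = 9)
  sim <- simulate_study(cfg)
  truth_lab <- unlist(unname(lapply(names(sim$truth$modules), function(m)
    setNames(rep(m, length(sim$truth$modules[[m]])), sim$truth$modules[[m]]))))
  net_genes <- names(truth_lab)
  res <- coexpression_modules(sim$study, net_genes, k = 3, n_restarts = 8,
                              max_iter = 500, tol = 1e-5, seed = 10)
  got <- unlist(unname(lapply(res$modules, function(m)
    setNames(rep(m$module_id, nrow(m$members)), m$members$gene_id))))
  expect_gte(ari(got[net_genes], truth_lab[net_genes]), 0.8)
})

test_that("module annotation flags matched terms and tolerates PCG-free modules", {
  cfg <- simulation_config(n_lnc = 30, n_pcg = 80, n_modules = 2,
                           module_size_lnc = 8, module_size_pcg = 25,
                           module_factor_sd = 1, de_fraction = 0, de_logfc = 0,
                           noise_sd = 0.3,
                           n_samples_per_group = c("CTR" = 10, "MDS-MLD" = 20),
                           mutation_carriers = c(), mutation_de_genes = 0,
                           include_anchors = FALSE, n_unscreened_patients = 0,
                           n_unscreened_controls = 0,
                           n_terms = 15, term_enrichment = 0.9, seed = 11)
  sim <- simulate_study(cfg)
  ann <- simulate_annotation(sim$truth, cfg)
  net_genes <- unlist(sim$truth$modules)
  res <- coexpression_modules(sim$study, net_genes, k = 2, n_restarts = 8,
                              max_iter = 500, tol = 1e-5, seed = 12)
  universe <- intersect(net_genes,
                        sim$study$genes$gene_id[sim$study$genes$biotype == "PCG"])
  mods <- annotate_modules(res$modules, ann$term_table, universe)
  matched_found <- vapply(mods, function(m)
    any(m$enriched_terms$term %in% ann$matched_terms), TRUE)
  expect_true(any(matched_found))
  # module without annotated PCGs yields an empty annotation with a warning
  fake <- list(list(module_id = "MX",
                    members = data.frame(gene_id = "LNC00001",
                                         biotype = "lncRNA", membership = 1),
                    core_lncRNAs = "LNC00001", core_PCGs = character(0),
                    enriched_terms = NULL))
  expect_warning(out <- annotate_modules(fake, ann$term_table, universe),
                 "no annotated PCG")
  expect_equal(nrow(out[[1]]$enriched_terms), 0)
})

test_that("lncRNA-centred networks separate and join foci as constructed", {
  set.seed(13)
  n_s <- 40
  f1 <- rnorm(n_s); f2 <- rnorm(n_s)
  n_pcg <- 30
  mat <- rbind(
    FOCA = 7 + f1 + rnorm(n_s, 0, 0.3),
    FOCB = 7 + f1 + rnorm(n_s, 0, 0.3),
    FOCC = 7 + f2 + rnorm(n_s, 0, 0.3))
  for (i in seq_len(n_pcg)) {
    f <- if (i <= 15) f1 else f2
    mat <- rbind(mat, 7 + f + rnorm(n_s, 0, 0.3))
  }
  rownames(mat) <- c("FOCA", "FOCB", "FOCC", sprintf("P%02d", seq_len(n_pcg)))
  colnames(mat) <- sprintf("S%02d", seq_len(n_s))
  genes <- data.frame(gene_id = rownames(mat),
                      biotype = c(rep("lncRNA", 3), rep("PCG", n_pcg)),
                      partner_id = NA_character_)
  samples <- data.frame(sample_id = colnames(mat),
                        group = rep(c("CTR", "MDS-MLD"), each = n_s / 2))
  study <- expression_study(mat, genes, samples)
  de_ids <- rownames(mat)
  # foci on the same latent factor land in one module
  res_ab <- lncrna_centered_network(study, c("FOCA", "FOCB"), de_ids,
                                    q = 10, k = 2, seed = 14)
  joint <- Filter(function(f) length(f) == 2, res_ab$focus_cooccupancy)
  expect_length(joint, 1)
  # foci on independent factors split into separate modules
  res_ac <- lncrna_centered_network(study, c("FOCA", "FOCC"), de_ids,
                                    q = 10, k = 2, seed = 15)
  expect_length(res_ac$modules, 2)
  expect_true(all(lengths(res_ac$focus_cooccupancy) == 1))
  # q larger than the available PCGs simply uses them all
  res_big <- lncrna_centered_network(study, "FOCA", de_ids, q = 500,
                                     k = 2, seed = 16)
  expect_gt(length(res_big$modules), 0)
  expect_error(lncrna_centered_network(study, "NOPE", de_ids), "NOPE")
})
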