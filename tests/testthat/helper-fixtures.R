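# shared fixture builders and small independent oracles

make_small_study <- function(n_lnc = 3, n_pcg = 3, n_samples = 6,
                             groups = NULL, seed = 1) {
  set.seed(seed)
  n_g <- n_lnc + n_pcg
  ids <- c(sprintf("LNC%02d", seq_len(n_lnc)), sprintf("PCG%02d", seq_len(n_pcg)))
  mat <- matrix(rnorm(n_g * n_samples, 7, 1), n_g, n_samples,
                dimnames = list(ids, sprintf("S%02d", seq_len(n_samples))))
  if (is.null(groups)) {
    groups <- rep(c("CTR", "MDS-MLD"), length.out = n_samples)
  }
  genes <- data.frame(gene_id = ids,
                      biotype = rep(c("lncRNA", "PCG"), c(n_lnc, n_pcg)),
                      partner_id = NA_character_, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(mat), group = groups,
                        ipssr_score = NA_real_, ipssr_category = NA_character_,
                        karyotype = NA_character_,
                        os_months = NA_real_, os_event = NA,
                        pfs_months = NA_real_, pfs_event = NA,
                        age = 70, blast_pct = 5, hemoglobin = 100,
                        neutrophils = 2, platelets = 150,
                        stringsAsFactors = FALSE)
  expression_study(mat, genes, samples)
}

# adjusted Rand index, written directly from the pair-counting formula
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  row_c <- sum_comb(rowSums(tab))
  col_c <- sum_comb(colSums(tab))
  expected <- row_c * col_c / choose(n, 2)
  max_idx <- (row_c + col_c) / 2
  if (max_idx == expected) return(1)
  (idx - expected) / (max_idx - expected)
}

# direct BH step-up evaluation, independent of stats::p.adjust
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# brute-force GSEA running sum: explicit loop over positions
brute_force_es <- function(gene_ids, scores, gene_set, weight_p = 1) {
  n <- length(gene_ids)
  hit <- gene_ids %in% gene_set
  nh <- sum(hit)
  denom <- sum(abs(scores[hit])^weight_p)
  rs <- numeric(n)
  run <- 0
  for (j in seq_len(n)) {
    run <- run + if (hit[j]) abs(scores[j])^weight_p / denom else -1 / (n - nh)
    rs[j] <- run
  }
  rs[which.max(abs(rs))]
}

# exhaustive hypergeometric upper tail: enumerate all draws of size n
enumerate_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_term <- seq_len(K)  # first K population members are in the term
  hits <- apply(draws, 2, function(d) sum(d %in% in_term))
  mean(hits >= k)
}
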