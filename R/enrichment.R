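#' GSEA weighted running-sum enrichment score
#'
#' Walks the ranking from top to bottom, adding `|r_j|^p / sum_hits |r|^p` at
#' set members (hits) and subtracting `1 / (N - N_H)` at non-members. The
#' enrichment score is the running-sum extremum of largest magnitude; the
#' leading edge comprises the members at or before the extremum (positive ES)
#' or at or after it (negative ES). `weight_p = 0` reduces to the classical
#' Kolmogorov-Smirnov statistic between hit and miss positions.
#'
#' @param gene_ids character vector, the ranked gene list (best first).
#' @param scores numeric ranking metric aligned with `gene_ids`.
#' @param gene_set character vector of member gene ids.
#' @param weight_p hit-weight exponent (default 1).
#' @return list with `ES`, `running_sum` (length N), `leading_edge` and
#'   `peak` (index of the extremum).
#' @export
gsea_enrichment_score <- function(gene_ids, scores, gene_set, weight_p = 1) {
  stopifnot(length(gene_ids) == length(scores), all(is.finite(scores)))
  hit <- gene_ids %in% gene_set
  n <- length(gene_ids)
  n_h <- sum(hit)
  if (n_h == 0) stop("gene set has no member in the ranking")
  if (n_h == n) stop("gene set covers the whole ranking")
  w <- abs(scores)^weight_p
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (n - n_h))
  rs <- cumsum(inc)
  peak <- which.max(abs(rs))
  es <- rs[peak]
  leading <- if (es >= 0) gene_ids[hit & seq_len(n) <= peak] else
    gene_ids[hit & seq_len(n) >= peak]
  list(ES = es, running_sum = rs, leading_edge = leading, peak = peak)
}

rank_by_moderated_t <- function(study, ctr) {
  de <- moderated_t_contrast(study, ctr)
  ord <- order(-de$t_mod, de$gene_id)
  list(gene_ids = de$gene_id[ord], scores = de$t_mod[ord])
}

#' Permutation GSEA over a contrast
#'
#' Ranks all genes by the contrast's moderated t, scores each gene set with
#' the weighted running sum, and assesses significance by phenotype-label
#' permutation (group labels reshuffled, ranking recomputed per permutation).
#' When either group has fewer than `min_group_perm` samples the sample-label
#' space is too small and gene-set (ranking-position) permutation is used
#' instead, with a warning. `NES = ES / mean(|permuted ES| of the same
#' sign)`; the permutation p is one-sided within sign; FDR is computed per
#' sign pool by BH over the permutation p-values.
#'
#' @param study an `ExpressionStudy`.
#' @param ctr a [contrast()].
#' @param gene_sets named list of member vectors (e.g. from [read_gmt()]).
#' @param n_perm number of permutations (default 1000).
#' @param weight_p hit-weight exponent (default 1).
#' @param min_group_perm minimum per-group size for phenotype permutation
#'   (default 7).
#' @param seed integer RNG seed.
#' @return data.frame: `set`, `size`, `ES`, `NES`, `p_perm`, `q`,
#'   `leading_edge` (semicolon-joined).
#' @export
gsea_significance <- function(study, ctr, gene_sets, n_perm = 1000,
                              weight_p = 1, min_group_perm = 7, seed = 1L) {
  stopifnot(inherits(ctr, "Contrast"), length(gene_sets) >= 1)
  set.seed(seed)
  rk <- rank_by_moderated_t(study, ctr)
  obs <- lapply(gene_sets, function(gs)
    gsea_enrichment_score(rk$gene_ids, rk$scores, gs, weight_p))
  es <- vapply(obs, `[[`, 0, "ES")

  phenotype <- min(length(ctr$samples_a), length(ctr$samples_b)) >= min_group_perm
  if (!phenotype) {
    warning("group too small for phenotype permutation; ",
            "falling back to gene-set permutation")
  }
  all_ids <- c(ctr$samples_a, ctr$samples_b)
  na <- length(ctr$samples_a)
  perm_es <- matrix(NA_real_, nrow = n_perm, ncol = length(gene_sets))
  for (b in seq_len(n_perm)) {
    if (phenotype) {
      idx <- sample(all_ids)
      pctr <- contrast(ctr$name, idx[seq_len(na)], idx[-seq_len(na)],
                       ctr$lfc_threshold, ctr$fdr_threshold)
      prk <- rank_by_moderated_t(study, pctr)
      perm_es[b, ] <- vapply(gene_sets, function(gs)
        gsea_enrichment_score(prk$gene_ids, prk$scores, gs, weight_p)$ES, 0)
    } else {
      perm_es[b, ] <- vapply(gene_sets, function(gs) {
        fake <- sample(rk$gene_ids, length(intersect(gs, rk$gene_ids)))
        gsea_enrichment_score(rk$gene_ids, rk$scores, fake, weight_p)$ES
      }, 0)
    }
  }

  nes <- p_perm <- numeric(length(es))
  for (j in seq_along(es)) {
    same_sign <- if (es[j] >= 0) perm_es[, j][perm_es[, j] >= 0] else
      perm_es[, j][perm_es[, j] < 0]
    denom <- mean(abs(same_sign))
    nes[j] <- if (isTRUE(denom > 0)) es[j] / denom else NA_real_
    p_perm[j] <- if (length(same_sign)) {
      (1 + sum(abs(same_sign) >= abs(es[j]))) / (1 + length(same_sign))
    } else 1 / (1 + n_perm)
  }
  q <- rep(NA_real_, length(es))
  pos <- which(es >= 0); neg <- which(es < 0)
  if (length(pos)) q[pos] <- benjamini_hochberg(p_perm[pos])
  if (length(neg)) q[neg] <- benjamini_hochberg(p_perm[neg])
  data.frame(set = names(gene_sets),
             size = vapply(gene_sets, function(gs)
               length(intersect(gs, rk$gene_ids)), 0L),
             ES = es, NES = nes, p_perm = p_perm, q = q,
             leading_edge = vapply(obs, function(o)
               paste(o$leading_edge, collapse = ";"), ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation of annotation terms in a gene module
#'
#' Upper-tail hypergeometric test per term: with population `N = |universe|`,
#' `K = |term|` annotated genes, `n = |module|` draws and `k` observed
#' members, `p = P[X >= k]`. Terms are reported sorted by ascending p; the
#' `significant` column flags `p < p_threshold` (raw p by design, with a BH
#' column emitted alongside for transparency).
#'
#' @param module_genes character vector of module member ids.
#' @param term_table data.frame with columns `gene_id`, `term`.
#' @param universe character vector, the eligible gene background.
#' @param p_threshold raw-p significance threshold (default 0.01).
#' @return data.frame: `term`, `k`, `K`, `n`, `N`, `p`, `q`, `significant`.
#' @export
hypergeometric_enrichment <- function(module_genes, term_table, universe,
                                      p_threshold = 0.01) {
  if (!length(module_genes)) stop("empty module")
  module_genes <- intersect(module_genes, universe)
  term_table <- term_table[term_table$gene_id %in% universe, , drop = FALSE]
  n_pop <- length(unique(universe))
  n_draw <- length(unique(module_genes))
  terms <- unique(term_table$term)
  res <- lapply(terms, function(tm) {
    members <- unique(term_table$gene_id[term_table$term == tm])
    k_obs <- length(intersect(module_genes, members))
    p <- stats::phyper(k_obs - 1, length(members), n_pop - length(members),
                       n_draw, lower.tail = FALSE)
    data.frame(term = tm, k = k_obs, K = length(members), n = n_draw,
               N = n_pop, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, out$term), , drop = FALSE]
  out$q <- benjamini_hochberg(out$p)
  out$significant <- out$p < p_threshold
  rownames(out) <- NULL
  out
}
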