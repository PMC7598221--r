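#' Define a two-group contrast
#'
#' @param name contrast label.
#' @param samples_a,samples_b disjoint character vectors of sample ids, each
#'   of size >= 2. `logFC` is reported as group A minus group B.
#' @param lfc_threshold absolute log2 fold-change threshold for significance
#'   calls (default 1).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return a `Contrast` list.
#' @export
contrast <- function(name, samples_a, samples_b,
                     lfc_threshold = 1, fdr_threshold = 0.05) {
  stopifnot(lfc_threshold > 0, fdr_threshold > 0, fdr_threshold < 1)
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    stop("each contrast group needs >= 2 samples")
  }
  if (length(intersect(samples_a, samples_b))) {
    stop("contrast groups overlap: ",
         paste(intersect(samples_a, samples_b), collapse = ", "))
  }
  structure(list(name = name, samples_a = samples_a, samples_b = samples_b,
                 lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold),
            class = "Contrast")
}

#' Filter undetected genes
#'
#' Keeps genes whose signal exceeds `min_signal` in at least `min_fraction`
#' of samples. Defaults follow the package convention: the matrix 10th
#' percentile as the signal floor, detection in at least 10% of samples.
#'
#' @param study an `ExpressionStudy`.
#' @param min_signal detection floor on the log2 scale (default: 10th
#'   percentile of the whole matrix).
#' @param min_fraction minimum fraction of samples above the floor.
#' @return the filtered `ExpressionStudy`.
#' @export
detection_filter <- function(study,
                             min_signal = stats::quantile(study$matrix, 0.1),
                             min_fraction = 0.1) {
  frac <- rowMeans(study$matrix > min_signal)
  keep <- frac >= min_fraction
  if (!any(keep)) stop("detection filter removed every gene")
  message("detection filter kept ", sum(keep), " of ", length(keep), " genes")
  subset_study(study, gene_ids = study$genes$gene_id[keep])
}

#' Collapse duplicate probes to one row per gene
#'
#' Probes mapping to the same gene are merged to their per-sample median.
#' Row order of the result follows the first appearance of each gene.
#'
#' @param mat numeric probes x samples matrix.
#' @param gene_ids character vector of length `nrow(mat)`, the gene each
#'   probe measures (repeats allowed).
#' @return a genes x samples matrix with unique rownames.
#' @export
collapse_duplicates <- function(mat, gene_ids) {
  stopifnot(nrow(mat) == length(gene_ids))
  uniq <- unique(gene_ids)
  out <- matrix(NA_real_, nrow = length(uniq), ncol = ncol(mat),
                dimnames = list(uniq, colnames(mat)))
  for (g in uniq) {
    rows <- which(gene_ids == g)
    out[g, ] <- if (length(rows) == 1L) mat[rows, ] else
      apply(mat[rows, , drop = FALSE], 2, stats::median)
  }
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# method-of-moments fit of the scaled inverse-chi-square variance prior:
# z_g = log s2_g has mean log s2_0 - digamma(d0/2) + log(d0/2) (shifted by the
# per-gene digamma term) and excess variance trigamma(d0/2)
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & df > 0
  if (!any(ok)) stop("no positive residual variances to fit the prior")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  ebar <- mean(e)
  n <- length(e)
  if (n < 2) return(list(d0 = 0, s2_0 = mean(s2[ok])))
  target <- mean((e - ebar)^2 * n / (n - 1) - trigamma(df[ok] / 2))
  if (target <= 0) {
    # observed spread no larger than sampling noise: fully pooled prior
    return(list(d0 = Inf, s2_0 = mean(s2[ok])))
  }
  x <- trigamma_inverse(target)
  list(d0 = 2 * x, s2_0 = exp(ebar + digamma(x) - log(x)))
}

# solve trigamma(x) = y for x > 0 by Newton iteration on the inverse scale
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated t contrast
#'
#' Per gene: `logFC = mean_a - mean_b`; pooled residual variance `s2_g` on
#' `d_g = n_a + n_b - 2` df; the variance prior `(d0, s2_0)` is fitted by the
#' method of moments on `log s2_g` (digamma/trigamma closed forms); posterior
#' variance `s2_post = (d0 s2_0 + d_g s2_g) / (d0 + d_g)`; the moderated
#' statistic `t = logFC / sqrt(s2_post (1/n_a + 1/n_b))` is referred to a t
#' distribution on `d0 + d_g` df (normal when the prior df are infinite).
#'
#' @param study an `ExpressionStudy`.
#' @param ctr a [contrast()].
#' @return data.frame (one row per gene): `gene_id`, `biotype`, `logFC`,
#'   `s2_g`, `d_g`, `s2_post`, `d0`, `s2_0`, `t_mod`, `p`, `q`, `significant`.
#' @export
moderated_t_contrast <- function(study, ctr) {
  stopifnot(inherits(ctr, "Contrast"))
  a <- study$matrix[, ctr$samples_a, drop = FALSE]
  b <- study$matrix[, ctr$samples_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  logfc <- rowMeans(a) - rowMeans(b)
  d_g <- na + nb - 2
  ssa <- rowSums((a - rowMeans(a))^2)
  ssb <- rowSums((b - rowMeans(b))^2)
  s2 <- (ssa + ssb) / d_g
  if (all(s2 == 0)) stop("zero residual variance in every gene")
  if (nrow(study$matrix) == 1L) {
    warning("single gene: falling back to the ordinary pooled t (d0 = 0)")
    prior <- list(d0 = 0, s2_0 = s2)
  } else {
    prior <- fit_variance_prior(s2, rep(d_g, length(s2)))
  }
  d0 <- prior$d0
  if (is.infinite(d0)) {
    s2_post <- rep(prior$s2_0, length(s2))
    df_tot <- Inf
  } else {
    s2_post <- (d0 * prior$s2_0 + d_g * s2) / (d0 + d_g)
    df_tot <- d0 + d_g
  }
  t_mod <- logfc / sqrt(s2_post * (1 / na + 1 / nb))
  p <- if (is.infinite(df_tot)) 2 * stats::pnorm(-abs(t_mod)) else
    2 * stats::pt(-abs(t_mod), df_tot)
  q <- benjamini_hochberg(p)
  data.frame(gene_id = study$genes$gene_id, biotype = study$genes$biotype,
             logFC = logfc, s2_g = s2, d_g = d_g, s2_post = s2_post,
             d0 = d0, s2_0 = prior$s2_0, t_mod = t_mod, p = p, q = q,
             significant = abs(logfc) > ctr$lfc_threshold & q < ctr$fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition DE results into up/down/non-significant calls per biotype
#'
#' Up means `logFC > +threshold` with `q < fdr`; down is the mirror image;
#' both inequalities are strict.
#'
#' @param results data.frame from [moderated_t_contrast()].
#' @param ctr the [contrast()] supplying the thresholds.
#' @return list with `up`, `down`, `ns` (character vectors of gene ids) and
#'   `counts`, a biotype x direction table.
#' @export
call_significant <- function(results, ctr) {
  up <- results$logFC > ctr$lfc_threshold & results$q < ctr$fdr_threshold
  down <- results$logFC < -ctr$lfc_threshold & results$q < ctr$fdr_threshold
  dir <- ifelse(up, "up", ifelse(down, "down", "ns"))
  counts <- table(biotype = results$biotype,
                  direction = factor(dir, levels = c("up", "down", "ns")))
  list(up = results$gene_id[up], down = results$gene_id[down],
       ns = results$gene_id[!(up | down)], counts = counts)
}

#' One-way ANOVA expression profile across sample groups
#'
#' Classical one-way F statistic per gene across the study's sample groups,
#' BH-adjusted across genes, with per-group mean log2 levels and their
#' difference from the control-group mean (the heatmap scale).
#'
#' @param study an `ExpressionStudy`.
#' @param ctr_group label of the reference group (default `"CTR"`).
#' @param min_group_size groups smaller than this are excluded with a warning
#'   (default 2).
#' @return list with `table` (gene_id, F, p, q), `group_means` (genes x
#'   groups) and `logfc_vs_ctr` (genes x groups, reference column all zero).
#' @export
anova_profile <- function(study, ctr_group = "CTR", min_group_size = 2) {
  grp <- study$samples$group
  sizes <- table(grp)
  small <- names(sizes)[sizes < min_group_size]
  if (length(small)) {
    warning("excluding group(s) with < ", min_group_size, " samples: ",
            paste(small, collapse = ", "))
  }
  keep_g <- setdiff(names(sizes), small)
  if (length(keep_g) < 2) stop("need >= 2 groups with >= ", min_group_size, " samples")
  keep <- grp %in% keep_g
  x <- study$matrix[, keep, drop = FALSE]
  g <- factor(grp[keep], levels = keep_g)
  n <- ncol(x)
  k <- nlevels(g)
  means <- vapply(levels(g), function(l) rowMeans(x[, g == l, drop = FALSE]),
                  numeric(nrow(x)))
  grand <- rowMeans(x)
  n_per <- as.integer(table(g))
  ss_between <- as.numeric((means - grand)^2 %*% n_per)
  ss_total <- rowSums((x - grand)^2)
  ss_within <- ss_total - ss_between
  f_stat <- (ss_between / (k - 1)) / (ss_within / (n - k))
  p <- stats::pf(f_stat, k - 1, n - k, lower.tail = FALSE)
  q <- benjamini_hochberg(p)
  if (!ctr_group %in% colnames(means)) {
    stop("reference group ", ctr_group, " not among the analysed groups")
  }
  logfc <- means - means[, ctr_group]
  list(table = data.frame(gene_id = study$genes$gene_id, F = f_stat,
                          p = p, q = q, row.names = NULL,
                          stringsAsFactors = FALSE),
       group_means = means, logfc_vs_ctr = logfc)
}

#' Cluster sample groups by their significant-gene profiles
#'
#' Hierarchical clustering (average linkage, Euclidean distance) of the
#' group-mean logFC-versus-control vectors restricted to ANOVA-significant
#' genes, cut to `n_clusters` flat clusters.
#'
#' @param anova_res result of [anova_profile()].
#' @param n_clusters number of flat clusters (default 3).
#' @param fdr_threshold ANOVA significance threshold on `q` (default 0.05).
#' @return list with `hclust` (the dendrogram), `clusters` (named integer
#'   vector group -> cluster) and `n_significant`.
#' @export
cluster_groups <- function(anova_res, n_clusters = 3, fdr_threshold = 0.05) {
  sig <- anova_res$table$q < fdr_threshold
  if (sum(sig) < 2) stop("fewer than 2 ANOVA-significant genes")
  prof <- t(anova_res$logfc_vs_ctr[sig, , drop = FALSE])
  hc <- stats::hclust(stats::dist(prof, method = "euclidean"),
                      method = "average")
  if (n_clusters > nrow(prof)) stop("more clusters requested than groups")
  cl <- stats::cutree(hc, k = n_clusters)
  list(hclust = hc, clusters = cl, n_significant = sum(sig))
}
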