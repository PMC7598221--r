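#' Cis-pair correlations within sample subgroups
#'
#' Spearman correlation (with its t-approximation p) of each transcript pair
#' inside each requested subgroup of samples. Subgroups with fewer than
#' `min_samples` members yield missing cells with a warning.
#'
#' @param study an `ExpressionStudy`.
#' @param pairs list of length-2 character vectors of gene ids (e.g.
#'   `list(c("WT1", "WT1-AS"))`).
#' @param subgroups named list of sample-id vectors.
#' @param min_samples minimum subgroup size (default 4).
#' @return data.frame: `gene_x`, `gene_y`, `subgroup`, `n`, `r`, `p`.
#' @export
cis_pair_correlation <- function(study, pairs, subgroups, min_samples = 4) {
  rows <- list()
  for (pr in pairs) {
    miss <- setdiff(pr, study$genes$gene_id)
    if (length(miss)) stop("gene not in study: ", paste(miss, collapse = ", "))
    gx <- study$matrix[match(pr[1], study$genes$gene_id), ]
    gy <- study$matrix[match(pr[2], study$genes$gene_id), ]
    for (nm in names(subgroups)) {
      ids <- subgroups[[nm]]
      idx <- match(ids, study$samples$sample_id)
      if (length(idx) < min_samples) {
        warning("subgroup ", nm, " below ", min_samples, " samples")
        rows[[length(rows) + 1L]] <- data.frame(
          gene_x = pr[1], gene_y = pr[2], subgroup = nm, n = length(idx),
          r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      rp <- spearman_rp(gx[idx], gy[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_x = pr[1], gene_y = pr[2], subgroup = nm, n = length(idx),
        r = rp$r, p = rp$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify samples as concordant or discordant for a transcript pair
#'
#' The per-sample linear-scale ratio is `2^(x - y)`; the reference ratio is
#' the median ratio over the reference samples (healthy controls by
#' default). A sample is discordant iff the fold change of its ratio against
#' the reference exceeds 10 in either direction (`> 10` or `< 0.1`, both
#' strict, so an exactly 10-fold change is concordant).
#'
#' @param study an `ExpressionStudy`.
#' @param gene_x,gene_y the transcript pair (e.g. `"H19"`, `"IGF2"`).
#' @param reference_ids sample ids defining the reference ratio (must be
#'   non-empty).
#' @param fold_threshold discordance threshold (default 10).
#' @return data.frame: `sample_id`, `ratio`, `ref_ratio`,
#'   `fold_change_of_ratio`, `label` (`"concordant"`/`"discordant"`).
#' @export
classify_concordance <- function(study, gene_x, gene_y, reference_ids,
                                 fold_threshold = 10) {
  miss <- setdiff(c(gene_x, gene_y), study$genes$gene_id)
  if (length(miss)) stop("gene not in study: ", paste(miss, collapse = ", "))
  if (!length(reference_ids)) stop("reference set is empty")
  x <- study$matrix[match(gene_x, study$genes$gene_id), ]
  y <- study$matrix[match(gene_y, study$genes$gene_id), ]
  log_ratio <- x - y
  ref_idx <- match(reference_ids, study$samples$sample_id)
  if (anyNA(ref_idx)) stop("unknown reference sample id")
  ref_ratio <- 2^stats::median(log_ratio[ref_idx])
  ratio <- 2^log_ratio
  fc <- ratio / ref_ratio
  data.frame(sample_id = study$samples$sample_id,
             ratio = ratio, ref_ratio = ref_ratio,
             fold_change_of_ratio = fc,
             label = ifelse(fc > fold_threshold | fc < 1 / fold_threshold,
                            "discordant", "concordant"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Log-rank survival comparison of concordant vs discordant patients
#'
#' @param study an `ExpressionStudy` with survival endpoints.
#' @param calls data.frame from [classify_concordance()].
#' @param endpoints endpoints to test (default both `"os"` and `"pfs"`).
#' @return data.frame: `endpoint`, `n_concordant`, `n_discordant`, `chi2`,
#'   `p` (`NA` with a warning when only one label class is present).
#' @export
discordance_survival_test <- function(study, calls,
                                      endpoints = c("os", "pfs")) {
  s <- study$samples
  rows <- lapply(endpoints, function(ep) {
    time <- s[[paste0(ep, "_months")]]
    event <- s[[paste0(ep, "_event")]]
    lab <- calls$label[match(s$sample_id, calls$sample_id)]
    ok <- s$group != "CTR" & !is.na(time) & !is.na(event) & !is.na(lab)
    conc <- ok & lab == "concordant"
    disc <- ok & lab == "discordant"
    if (!any(conc) || !any(disc)) {
      warning("single-class labelling for ", ep, ": p undefined")
      return(data.frame(endpoint = ep, n_concordant = sum(conc),
                        n_discordant = sum(disc), chi2 = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    lr <- logrank_test(time[conc], event[conc], time[disc], event[disc])
    data.frame(endpoint = ep, n_concordant = sum(conc),
               n_discordant = sum(disc), chi2 = lr$chi2, p = lr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
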