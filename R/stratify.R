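#' Stratify patients by overall survival at a cut-off
#'
#' Splits MDS/AML-MRC patients into short survivors (deceased at or before the
#' cut-off), long survivors (observed beyond the cut-off, dead or alive) and
#' excluded samples. A death at exactly the cut-off counts as short survival.
#' Patients censored at or before the cut-off carry no information about which
#' side they belong to and are excluded, as are healthy controls and samples
#' without follow-up.
#'
#' @param study an `ExpressionStudy`.
#' @param cutoff_months survival cut-off in months (default 18).
#' @return list with character vectors `short`, `long`, `excluded`.
#' @export
stratify_by_survival <- function(study, cutoff_months = 18) {
  s <- study$samples
  patient <- s$group != "CTR"
  if (!any(patient)) stop("no MDS/AML samples to stratify")
  os <- s$os_months
  ev <- s$os_event
  short <- patient & !is.na(os) & !is.na(ev) & ev & os <= cutoff_months
  long <- patient & !is.na(os) & os > cutoff_months
  excluded <- !(short | long)
  n_cens <- sum(patient & !is.na(os) & !is.na(ev) & !ev & os <= cutoff_months)
  if (n_cens) {
    message(n_cens, " patient(s) censored at or before ", cutoff_months,
            " months excluded from the survival stratification")
  }
  list(short = s$sample_id[short], long = s$sample_id[long],
       excluded = s$sample_id[excluded])
}

#' Stratify MDS patients into lower- vs higher-risk IPSS-R categories
#'
#' Lower risk pools the very-low and low IPSS-R categories, higher risk the
#' high and very-high categories. Intermediate-risk MDS, AML-MRC, controls and
#' samples without an IPSS-R category are excluded.
#'
#' @param study an `ExpressionStudy`.
#' @return list with character vectors `lower`, `higher`, `excluded`.
#' @export
stratify_by_ipssr <- function(study) {
  s <- study$samples
  cat_ <- if (is.null(s$ipssr_category)) rep(NA_character_, nrow(s)) else s$ipssr_category
  eligible <- s$group %in% mds_groups()
  lower <- eligible & !is.na(cat_) & cat_ %in% c("very_low", "low")
  higher <- eligible & !is.na(cat_) & cat_ %in% c("high", "very_high")
  excluded <- !(lower | higher)
  if (!any(lower) || !any(higher)) {
    message("empty IPSS-R stratum: lower=", sum(lower), " higher=", sum(higher))
  }
  list(lower = s$sample_id[lower], higher = s$sample_id[higher],
       excluded = s$sample_id[excluded])
}

#' Split screened samples into mutation carriers and wild type
#'
#' A sample is a carrier iff any recorded variant in `gene_symbol` has a
#' variant allele frequency strictly above `vaf_cutoff` (a variant at exactly
#' the cut-off is wild type). Unscreened samples (no mutation record) are
#' omitted from both sets.
#'
#' @param study an `ExpressionStudy`.
#' @param gene_symbol mutated gene of interest (e.g. `"SF3B1"`).
#' @param vaf_cutoff VAF fraction threshold (default 0.05, i.e. 5%).
#' @return list with character vectors `mutated` and `wildtype`.
#' @export
mutation_carrier_sets <- function(study, gene_symbol, vaf_cutoff = 0.05) {
  s <- study$samples
  screened <- !vapply(s$mutations, is.null, TRUE)
  if (!is.null(s$screened)) screened <- screened & s$screened
  carrier <- vapply(s$mutations, function(m) {
    !is.null(m) && gene_symbol %in% names(m) && any(m[names(m) == gene_symbol] > vaf_cutoff)
  }, TRUE)
  list(mutated = s$sample_id[screened & carrier],
       wildtype = s$sample_id[screened & !carrier])
}
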