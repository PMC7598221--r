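#' Expression study container
#'
#' Bundles a genes x samples log2 expression matrix with its gene annotation
#' and sample metadata. This is the universal input of the pipeline: every
#' downstream stage (differential expression, GSEA, coexpression modules,
#' survival models, concordance calls) consumes an `ExpressionStudy`.
#'
#' @param mat numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids), log2 intensities.
#' @param genes data.frame with columns `gene_id`, `biotype` (one of
#'   "lncRNA", "PCG", "miRNA") and optionally `partner_id` (sense/antisense or
#'   locus partner, empty string or NA when absent).
#' @param samples data.frame of sample metadata; must contain `sample_id` and
#'   `group`; clinical columns (`ipssr_score`, `ipssr_category`, `karyotype`,
#'   `os_months`, `os_event`, `pfs_months`, `pfs_event`, `age`, `blast_pct`,
#'   `hemoglobin`, `neutrophils`, `platelets`) may be missing (NA) per sample.
#'   A `mutations` list-column maps gene symbols to VAF fractions in [0,1].
#' @return an object of class `ExpressionStudy`.
#' @export
expression_study <- function(mat, genes, samples) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(genes$partner_id)) genes$partner_id <- NA_character_
  genes$partner_id[!is.na(genes$partner_id) & genes$partner_id == ""] <- NA_character_
  if (is.null(samples$mutations)) {
    samples$mutations <- replicate(nrow(samples), numeric(0), simplify = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(genes$biotype, c("lncRNA", "PCG", "miRNA"))
  if (length(bad)) stop("unknown biotype: ", paste(bad, collapse = ", "))
  miss_part <- setdiff(stats::na.omit(genes$partner_id), genes$gene_id)
  if (length(miss_part)) {
    stop("partner_id not present as gene_id: ", paste(miss_part, collapse = ", "))
  }
  if (nrow(mat) != nrow(genes)) stop("matrix has ", nrow(mat), " rows but ",
                                     nrow(genes), " gene annotations")
  if (ncol(mat) != nrow(samples)) stop("matrix has ", ncol(mat), " columns but ",
                                       nrow(samples), " sample records")
  if (is.null(rownames(mat))) rownames(mat) <- genes$gene_id
  if (is.null(colnames(mat))) colnames(mat) <- samples$sample_id
  extra <- setdiff(colnames(mat), samples$sample_id)
  if (length(extra)) stop("sample in matrix absent from metadata: ",
                          paste(extra, collapse = ", "))
  if (!identical(rownames(mat), genes$gene_id)) {
    stop("matrix rownames do not match annotation gene_id order")
  }
  if (!identical(colnames(mat), samples$sample_id)) {
    stop("matrix colnames do not match metadata sample_id order")
  }
  if (!all(is.finite(mat))) stop("expression matrix contains non-finite values")
  structure(list(matrix = mat, genes = genes, samples = samples),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  bt <- table(x$genes$biotype)
  cat("ExpressionStudy: ", nrow(x$matrix), " genes (",
      paste(sprintf("%s %d", names(bt), as.integer(bt)), collapse = ", "),
      ") x ", ncol(x$matrix), " samples\n", sep = "")
  gr <- table(x$samples$group)
  cat("groups:", paste(sprintf("%s=%d", names(gr), as.integer(gr)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionStudy <- function(x) dim(x$matrix)

#' Subset a study by genes and/or samples
#'
#' Keeps matrix, annotation and metadata consistent. Order of `gene_ids` /
#' `sample_ids` is respected in the result.
#'
#' @param study an `ExpressionStudy`.
#' @param gene_ids,sample_ids character vectors of ids to keep (default all).
#' @return a new `ExpressionStudy`.
#' @export
subset_study <- function(study, gene_ids = NULL, sample_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- study$genes$gene_id
  if (is.null(sample_ids)) sample_ids <- study$samples$sample_id
  miss <- setdiff(gene_ids, study$genes$gene_id)
  if (length(miss)) stop("unknown gene_id: ", paste(miss, collapse = ", "))
  miss <- setdiff(sample_ids, study$samples$sample_id)
  if (length(miss)) stop("unknown sample_id: ", paste(miss, collapse = ", "))
  gi <- match(gene_ids, study$genes$gene_id)
  si <- match(sample_ids, study$samples$sample_id)
  genes <- study$genes[gi, , drop = FALSE]
  rownames(genes) <- NULL
  samples <- study$samples[si, , drop = FALSE]
  rownames(samples) <- NULL
  # drop partner links that leave the subset rather than failing validation
  genes$partner_id[!(genes$partner_id %in% genes$gene_id)] <- NA_character_
  expression_study(study$matrix[gi, si, drop = FALSE], genes, samples)
}

#' Select samples by group membership
#'
#' @param study an `ExpressionStudy`.
#' @param groups character vector of group labels (e.g. `"CTR"`,
#'   `"MDS-EB2"`); `"MDS"` expands to all MDS-* subtypes.
#' @return character vector of sample ids, input order preserved.
#' @export
samples_in_groups <- function(study, groups) {
  g <- study$samples$group
  keep <- g %in% groups
  if ("MDS" %in% groups) keep <- keep | startsWith(g, "MDS-")
  study$samples$sample_id[keep]
}

mds_groups <- function() {
  c("MDS-SLD", "MDS-MLD", "MDS-RS", "MDS-del5q", "MDS-EB1", "MDS-EB2")
}

#' All WHO-style group labels used by the pipeline
#' @return character vector of the eight sample group labels.
#' @export
study_groups <- function() c("CTR", mds_groups(), "AML-MRC")
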