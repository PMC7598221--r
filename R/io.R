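#' Read an expression study from three TSV files
#'
#' The matrix TSV has `gene_id` as first column and one column per sample with
#' log2 values. The gene annotation TSV has columns `gene_id`, `biotype`,
#' `partner_id` (empty allowed). The sample metadata TSV carries the clinical
#' fields; the `mutations` column encodes a semicolon list `"GENE:VAF"`.
#' Missing clinical fields are preserved as NA, never imputed.
#'
#' @param matrix_path,gene_anno_path,sample_meta_path file paths.
#' @return an [expression_study()] object.
#' @export
read_expression_study <- function(matrix_path, gene_anno_path, sample_meta_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (colnames(raw)[1] != "gene_id") stop("matrix first column must be gene_id")
  gene_ids <- raw$gene_id
  vals <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1, dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric expression value at gene ", gene_ids[bad[1, 1]],
         ", sample ", colnames(vals)[bad[1, 2]])
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop("missing expression value at gene ", gene_ids[bad[1, 1]],
         ", sample ", colnames(vals)[bad[1, 2]])
  }
  mat <- num
  rownames(mat) <- gene_ids

  genes <- utils::read.delim(gene_anno_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  meta <- utils::read.delim(sample_meta_path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  meta$sample_id <- as.character(meta$sample_id)
  if (!is.null(meta$mutations)) {
    mut_str <- ifelse(is.na(meta$mutations), "", as.character(meta$mutations))
    meta$mutations <- lapply(mut_str, parse_mutation_string)
  }
  for (col in c("os_event", "pfs_event")) {
    if (!is.null(meta[[col]])) meta[[col]] <- as.logical(meta[[col]])
  }
  extra <- setdiff(colnames(mat), meta$sample_id)
  if (length(extra)) stop("sample in matrix absent from metadata: ",
                          paste(extra, collapse = ", "))
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  gmiss <- setdiff(gene_ids, genes$gene_id)
  if (length(gmiss)) stop("gene in matrix absent from annotation: ",
                          paste(utils::head(gmiss, 5), collapse = ", "))
  genes <- genes[match(gene_ids, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  expression_study(mat, genes, meta)
}

parse_mutation_string <- function(s) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed mutation entry: ", parts[bad][1])
  stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                  vapply(kv, `[`, "", 1L))
}

format_mutation_string <- function(m) {
  if (!length(m)) return("")
  paste(sprintf("%s:%s", names(m), format(m, trim = TRUE, scientific = FALSE)),
        collapse = ";")
}

#' Write an expression study to three TSV files
#'
#' Inverse of [read_expression_study()]; a write/read round trip reproduces
#' the matrix to full double precision and the metadata exactly.
#'
#' @param study an `ExpressionStudy`.
#' @param matrix_path,gene_anno_path,sample_meta_path output file paths.
#' @return invisibly, the paths written.
#' @export
write_expression_study <- function(study, matrix_path, gene_anno_path,
                                   sample_meta_path) {
  mat_df <- data.frame(gene_id = rownames(study$matrix),
                       study$matrix, check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.table(format(mat_df, digits = 17, trim = TRUE),
                     matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$genes, gene_anno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  meta <- study$samples
  meta$mutations <- vapply(meta$mutations, format_mutation_string, "")
  utils::write.table(meta, sample_meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(matrix_path, gene_anno_path, sample_meta_path))
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT dialect: set name, description, then member
#' gene ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors; the `description` attribute of
#'   each element carries the second column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields: ", f[1])
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set: ", f[1])
    attr(members, "description") <- f[2]
    out[[f[1]]] <- members
  }
  out
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute each).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column gene-to-term annotation table
#' @param path TSV with header columns `gene_id`, `term`.
#' @return data.frame with columns `gene_id` and `term`.
#' @export
read_term_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("gene_id", "term") %in% colnames(tab))) {
    stop("term table needs columns gene_id and term")
  }
  tab[, c("gene_id", "term")]
}
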