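#' Build the pairwise correlation matrix over DE transcripts
#'
#' Correlation of each pair of differentially expressed genes across the
#' selected samples. Exact symmetry is enforced by averaging the matrix with
#' its transpose; zero-variance genes are dropped with a warning.
#'
#' @param study an `ExpressionStudy`.
#' @param de_gene_ids character vector of DE gene ids entering the network.
#' @param sample_ids samples to correlate over (default: all study samples).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `C` (symmetric matrix, unit diagonal), `gene_ids` and
#'   `method`, of class `CorrelationMatrix`.
#' @export
build_correlation_matrix <- function(study, de_gene_ids,
                                     sample_ids = study$samples$sample_id,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(de_gene_ids) < 2) stop("need >= 2 DE genes")
  if (length(sample_ids) < 3) stop("need >= 3 samples")
  x <- study$matrix[match(de_gene_ids, study$genes$gene_id), sample_ids,
                    drop = FALSE]
  if (anyNA(x)) stop("unknown gene or sample id in the network request")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(de_gene_ids[sds == 0], collapse = ", "))
    x <- x[sds > 0, , drop = FALSE]
    de_gene_ids <- de_gene_ids[sds > 0]
  }
  c_mat <- stats::cor(t(x), method = method)
  c_mat <- (c_mat + t(c_mat)) / 2
  diag(c_mat) <- 1
  structure(list(C = c_mat, gene_ids = de_gene_ids, method = method),
            class = "CorrelationMatrix")
}

#' Map a correlation matrix to a nonnegative matrix
#'
#' Default mode `positive_clip` zeroes negative correlations, so modules
#' collect similarly regulated (co-up/co-down) genes; `abs` takes magnitudes
#' (conflating anti-correlation with correlation) and `shift` maps `[-1, 1]`
#' affinely to `[0, 1]`. The unit diagonal is retained.
#'
#' @param cm a `CorrelationMatrix` (or plain symmetric matrix in `[-1, 1]`).
#' @param mode one of `"positive_clip"`, `"abs"`, `"shift"`.
#' @return nonnegative symmetric matrix.
#' @export
nonnegative_transform <- function(cm, mode = c("positive_clip", "abs", "shift")) {
  mode <- match.arg(mode)
  c_mat <- if (inherits(cm, "CorrelationMatrix")) cm$C else cm
  switch(mode,
         positive_clip = pmax(c_mat, 0),
         abs = abs(c_mat),
         shift = (c_mat + 1) / 2)
}

nmf_objective <- function(a, w, h) sum((a - w %*% h)^2)

nmf_single_run <- function(a, k, max_iter, tol, record_objective = FALSE) {
  n <- nrow(a); m <- ncol(a)
  w <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  h <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  eps <- .Machine$double.eps
  obj <- nmf_objective(a, w, h)
  trace <- if (record_objective) obj else NULL
  for (it in seq_len(max_iter)) {
    h <- h * (t(w) %*% a) / (t(w) %*% w %*% h + eps)
    w <- w * (a %*% t(h)) / (w %*% (h %*% t(h)) + eps)
    new_obj <- nmf_objective(a, w, h)
    if (record_objective) trace <- c(trace, new_obj)
    if (obj - new_obj < tol * max(obj, eps)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  list(W = w, H = h, objective = obj, iterations = it, trace = trace)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius reconstruction error `||A - WH||_F^2` with the
#' classical multiplicative update rules from random nonnegative starts,
#' keeping the best of `n_restarts` runs. The objective is non-increasing at
#' every iteration; a run stops when the relative objective decrease falls
#' below `tol`.
#'
#' @param a nonnegative matrix (square for correlation input, but any shape
#'   is accepted).
#' @param k factorization rank, `2 <= k < min(dim(a))` (`k = 1` allowed for
#'   the rank-1 degenerate case).
#' @param n_restarts random restarts (default 30).
#' @param max_iter iteration cap per restart (default 2000).
#' @param tol relative objective-change convergence tolerance (default 1e-6).
#' @param seed integer RNG seed.
#' @param record_objective keep the per-iteration objective trace of each
#'   restart's winning run (for monotonicity checks).
#' @return list with `W` (n x k), `H` (k x m), `objective`, `iterations`
#'   and optionally `trace`.
#' @export
nmf_factorize <- function(a, k, n_restarts = 30, max_iter = 2000, tol = 1e-6,
                          seed = 1L, record_objective = FALSE) {
  stopifnot(all(a >= 0), k >= 1)
  if (k >= min(dim(a)) && k > 1) stop("rank k must be below the matrix dimension")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    run <- nmf_single_run(a, k, max_iter, tol, record_objective)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  best
}

argmax_assignment <- function(w, h) {
  m <- (w + t(h)) / 2
  m <- sweep(m, 2, sqrt(colSums(m^2)) + .Machine$double.eps, "/")
  apply(m, 1, which.max)
}

#' Choose the factorization rank by consensus cophenetic correlation
#'
#' For each candidate rank, runs `n_restarts` seeded factorizations, records
#' the co-assignment (argmax membership) consensus matrix, and scores its
#' cophenetic correlation under average-linkage clustering. The rank with the
#' highest cophenetic correlation wins; a maximum below 0.9 sets the
#' `low_confidence` flag.
#'
#' @param a nonnegative square matrix.
#' @param k_range candidate ranks (default 2:10, truncated to the dimension).
#' @param n_restarts restarts per rank (default 20).
#' @param max_iter,tol passed to the individual runs.
#' @param seed integer RNG seed.
#' @return list with `k` (selected rank), `diagnostics` (data.frame k,
#'   cophenetic) and `low_confidence`.
#' @export
select_rank <- function(a, k_range = 2:10, n_restarts = 20, max_iter = 500,
                        tol = 1e-5, seed = 1L) {
  k_range <- k_range[k_range >= 2 & k_range < nrow(a)]
  if (!length(k_range)) stop("no admissible rank in k_range")
  set.seed(seed)
  coph <- vapply(k_range, function(k) {
    consensus <- matrix(0, nrow(a), nrow(a))
    for (r in seq_len(n_restarts)) {
      run <- nmf_single_run(a, k, max_iter, tol)
      cl <- argmax_assignment(run$W, run$H)
      consensus <- consensus + outer(cl, cl, "==")
    }
    consensus <- consensus / n_restarts
    d <- stats::as.dist(1 - consensus)
    hc <- stats::hclust(d, method = "average")
    stats::cor(stats::cophenetic(hc), d)
  }, 0)
  best <- k_range[which.max(coph)]
  list(k = best,
       diagnostics = data.frame(k = k_range, cophenetic = coph),
       low_confidence = max(coph) < 0.9)
}

#' Assign genes to coexpression modules and extract representative cores
#'
#' Membership of gene `i` in module `m` is the column-normalized weight of
#' the symmetrized factor `(W + H^T) / 2` (for a symmetric input W and H are
#' near-transposes). Each gene goes to its argmax module, ties broken toward
#' the lowest module index; cores are the top-4 lncRNAs and top-13 PCGs by
#' membership within each module (fewer if the module is smaller), ties
#' broken by lexicographic gene id, listed in descending membership order.
#'
#' @param w,h NMF factors from [nmf_factorize()].
#' @param gene_ids character vector aligned with the rows of `w`.
#' @param biotypes biotype per gene (`"lncRNA"`, `"PCG"`, `"miRNA"`).
#' @param core_lnc,core_pcg core-size caps (defaults 4 and 13).
#' @return list of `CoexprModule` lists: `module_id`, `members` (data.frame
#'   gene_id, biotype, membership, sorted descending), `core_lncRNAs`,
#'   `core_PCGs`, `enriched_terms` (NULL until [annotate_modules()]).
#' @export
assign_modules <- function(w, h, gene_ids, biotypes, core_lnc = 4, core_pcg = 13) {
  stopifnot(nrow(w) == length(gene_ids), length(biotypes) == length(gene_ids))
  m <- (w + t(h)) / 2
  m <- sweep(m, 2, sqrt(colSums(m^2)) + .Machine$double.eps, "/")
  assign <- apply(m, 1, which.max)  # which.max takes the first (lowest) tie
  modules <- lapply(sort(unique(assign)), function(mod) {
    idx <- which(assign == mod)
    memb <- m[idx, mod]
    ord <- order(-memb, gene_ids[idx])
    members <- data.frame(gene_id = gene_ids[idx][ord],
                          biotype = biotypes[idx][ord],
                          membership = memb[ord],
                          stringsAsFactors = FALSE)
    core <- function(bt, cap) {
      ids <- members$gene_id[members$biotype == bt]
      utils::head(ids, cap)
    }
    list(module_id = sprintf("M%d", mod), members = members,
         core_lncRNAs = core("lncRNA", core_lnc),
         core_PCGs = core("PCG", core_pcg),
         enriched_terms = NULL)
  })
  names(modules) <- vapply(modules, `[[`, "", "module_id")
  modules
}

#' Annotate modules by term over-representation of their PCG members
#'
#' Applies [hypergeometric_enrichment()] to each module's PCG members against
#' the PCG universe of the network (guilt-by-association: terms enriched in a
#' module's PCGs are attributed to its lncRNAs).
#'
#' @param modules list from [assign_modules()].
#' @param term_table data.frame `gene_id`, `term`.
#' @param universe character vector of eligible PCG ids (all DE PCGs in the
#'   network).
#' @param p_threshold raw-p cut for reported terms (default 0.01).
#' @return the module list with `enriched_terms` filled (possibly zero-row).
#' @export
annotate_modules <- function(modules, term_table, universe, p_threshold = 0.01) {
  lapply(modules, function(mod) {
    pcgs <- mod$members$gene_id[mod$members$biotype == "PCG"]
    pcgs <- intersect(pcgs, universe)
    if (!length(pcgs)) {
      warning("module ", mod$module_id, " has no annotated PCG members")
      mod$enriched_terms <- data.frame(term = character(0), p = numeric(0))
      return(mod)
    }
    enr <- hypergeometric_enrichment(pcgs, term_table, universe, p_threshold)
    mod$enriched_terms <- enr[enr$significant, c("term", "k", "K", "p", "q"),
                              drop = FALSE]
    mod
  })
}

#' Full coexpression-module pipeline over a DE gene list
#'
#' Correlation matrix -> nonnegative transform -> rank selection (unless a
#' fixed `k` is given) -> NMF -> module assignment with core extraction.
#'
#' @param study an `ExpressionStudy`.
#' @param de_gene_ids DE genes entering the network.
#' @param sample_ids samples to correlate over (default all).
#' @param k fixed rank, or `NULL` for consensus-cophenetic selection.
#' @param transform nonnegative mode (see [nonnegative_transform()]).
#' @param method correlation method.
#' @param n_restarts,max_iter,tol NMF controls.
#' @param seed integer RNG seed.
#' @return list with `modules`, `correlation`, `factorization`, `k` and
#'   `rank_diagnostics` (NULL when `k` was fixed).
#' @export
coexpression_modules <- function(study, de_gene_ids,
                                 sample_ids = study$samples$sample_id,
                                 k = NULL, transform = "positive_clip",
                                 method = "pearson", n_restarts = 30,
                                 max_iter = 2000, tol = 1e-6, seed = 1L) {
  cm <- build_correlation_matrix(study, de_gene_ids, sample_ids, method)
  a <- nonnegative_transform(cm, transform)
  diag_tab <- NULL
  if (is.null(k)) {
    sel <- select_rank(a, seed = seed)
    k <- sel$k
    diag_tab <- sel$diagnostics
  }
  fit <- nmf_factorize(a, k, n_restarts = n_restarts, max_iter = max_iter,
                       tol = tol, seed = seed + 1L)
  bt <- study$genes$biotype[match(cm$gene_ids, study$genes$gene_id)]
  modules <- assign_modules(fit$W, fit$H, cm$gene_ids, bt)
  list(modules = modules, correlation = cm, factorization = fit, k = k,
       rank_diagnostics = diag_tab)
}

#' lncRNA-centred coexpression modules
#'
#' Runs the module pipeline on a reduced gene set: the focus lncRNAs plus,
#' per focus, its `q` most strongly correlated DE PCGs (by absolute
#' correlation). Only modules containing at least one focus are returned,
#' with a report of which foci co-occupy each module.
#'
#' @param study an `ExpressionStudy`.
#' @param focus_lncRNAs character vector of focus gene ids.
#' @param de_gene_ids the DE background from which partner PCGs are drawn.
#' @param q partner PCGs per focus (default 50; capped at availability).
#' @param sample_ids,k,transform,method,seed as in [coexpression_modules()].
#' @return list with `modules` (foci-containing only), `focus_cooccupancy`
#'   (module id -> foci), and `k`.
#' @export
lncrna_centered_network <- function(study, focus_lncRNAs, de_gene_ids, q = 50,
                                    sample_ids = study$samples$sample_id,
                                    k = NULL, transform = "positive_clip",
                                    method = "pearson", seed = 1L) {
  miss <- setdiff(focus_lncRNAs, study$genes$gene_id)
  if (length(miss)) stop("focus not expressed in the study: ",
                         paste(miss, collapse = ", "))
  pcg_ids <- intersect(de_gene_ids,
                       study$genes$gene_id[study$genes$biotype == "PCG"])
  pcg_ids <- setdiff(pcg_ids, focus_lncRNAs)
  partners <- character(0)
  for (fg in focus_lncRNAs) {
    fx <- study$matrix[fg, sample_ids]
    r <- apply(study$matrix[match(pcg_ids, study$genes$gene_id), sample_ids,
                            drop = FALSE], 1, function(y) stats::cor(fx, y))
    top <- pcg_ids[order(-abs(r), pcg_ids)][seq_len(min(q, length(pcg_ids)))]
    partners <- union(partners, top)
  }
  net_genes <- c(focus_lncRNAs, setdiff(partners, focus_lncRNAs))
  res <- coexpression_modules(study, net_genes, sample_ids = sample_ids,
                              k = k, transform = transform, method = method,
                              seed = seed)
  keep <- Filter(function(mod) any(focus_lncRNAs %in% mod$members$gene_id),
                 res$modules)
  occupancy <- lapply(keep, function(mod)
    intersect(focus_lncRNAs, mod$members$gene_id))
  list(modules = keep, focus_cooccupancy = occupancy, k = res$k)
}
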