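#' Resolve a named covariate from a study
#'
#' Resolution order: a numeric/logical column of the sample metadata (e.g.
#' `age`, `blast_pct`, `platelets`), then a gene id (log2 expression), then a
#' `mut_SYMBOL` pattern giving the mutation-carrier indicator at the 5% VAF
#' cut.
#'
#' @param study an `ExpressionStudy`.
#' @param name covariate name.
#' @return numeric vector aligned with the study samples (NA where missing).
#' @export
get_covariate <- function(study, name) {
  s <- study$samples
  if (name %in% colnames(s) && !identical(name, "mutations")) {
    return(as.numeric(s[[name]]))
  }
  if (name %in% study$genes$gene_id) {
    return(as.numeric(study$matrix[match(name, study$genes$gene_id), ]))
  }
  if (startsWith(name, "mut_")) {
    sym <- sub("^mut_", "", name)
    sets <- mutation_carrier_sets(study, sym)
    out <- rep(NA_real_, nrow(s))
    out[s$sample_id %in% sets$mutated] <- 1
    out[s$sample_id %in% sets$wildtype] <- 0
    return(out)
  }
  stop("unknown covariate: ", name)
}

#' Build complete-case survival records for an endpoint
#'
#' Patients (non-CTR) with the endpoint observed and every requested
#' covariate present; the number dropped for missingness is reported via
#' `message()`. Expression covariates are standardized (z-score over the
#' included patients) when `standardize_expression` is set, matching how
#' continuous expression enters the Cox models.
#'
#' @param study an `ExpressionStudy`.
#' @param endpoint `"os"` or `"pfs"`.
#' @param variables character vector of covariate names (see
#'   [get_covariate()]).
#' @param standardize_expression z-score covariates that are gene ids
#'   (default TRUE).
#' @return data.frame with `sample_id`, `time`, `event` and one column per
#'   covariate.
#' @export
survival_records <- function(study, endpoint = c("os", "pfs"), variables,
                             standardize_expression = TRUE) {
  endpoint <- match.arg(endpoint)
  s <- study$samples
  time <- s[[paste0(endpoint, "_months")]]
  event <- s[[paste0(endpoint, "_event")]]
  covs <- lapply(variables, function(v) get_covariate(study, v))
  names(covs) <- variables
  eligible <- s$group != "CTR"
  keep <- eligible & !is.na(time) & !is.na(event) & time > 0
  for (v in variables) keep <- keep & !is.na(covs[[v]])
  dropped <- sum(eligible) - sum(keep)
  if (dropped > 0) {
    message(dropped, " patient(s) dropped for missing endpoint/covariates")
  }
  rec <- data.frame(sample_id = s$sample_id[keep], time = time[keep],
                    event = as.logical(event[keep]),
                    stringsAsFactors = FALSE)
  for (v in variables) {
    x <- covs[[v]][keep]
    if (standardize_expression && v %in% study$genes$gene_id) {
      x <- as.numeric(scale(x))
    }
    rec[[v]] <- x
  }
  rec
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`; censoring
#' shrinks the risk set without a factor.
#'
#' @param time,event numeric event/censor times and logical event flags.
#' @return data.frame over distinct event times: `time`, `n_risk`,
#'   `n_event`, `surv`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  ts <- sort(unique(time[event]))
  n_risk <- vapply(ts, function(t) sum(time >= t), 0L)
  n_event <- vapply(ts, function(t) sum(time == t & event), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ts, n_risk = n_risk, n_event = n_event, surv = surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic with the hypergeometric variance summed
#' over distinct event times, referred to chi-square on 1 df.
#'
#' @param time_a,event_a,time_b,event_b per-group times and event flags.
#' @return list with `chi2`, `p`, `observed_a`, `expected_a`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop("both groups must be non-empty")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1L, 2L), c(length(time_a), length(time_b)))
  ts <- sort(unique(time[event]))
  if (!length(ts)) {
    warning("no events: log-rank undefined, p = 1")
    return(list(chi2 = 0, p = 1, observed_a = 0, expected_a = 0))
  }
  o_a <- e_a <- v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & grp == 1L)
    o_a <- o_a + d1
    e_a <- e_a + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) {
    warning("zero log-rank variance, p = 1")
    return(list(chi2 = 0, p = 1, observed_a = o_a, expected_a = e_a))
  }
  chi2 <- (o_a - e_a)^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       observed_a = o_a, expected_a = e_a)
}

#' Median (or maximally selected) dichotomization of a gene's expression
#'
#' Default rule: median split with ties to the low group. The `maxstat`
#' rule scans candidate cutpoints between the 10% and 90% expression
#' quantiles and picks the one maximizing the log-rank statistic on the
#' study's overall-survival endpoint.
#'
#' @param study an `ExpressionStudy`.
#' @param gene_id gene to split on.
#' @param rule `"median"` or `"maxstat"`.
#' @param sample_ids samples to split (default: all patients).
#' @return list with `low`, `high` (sample ids) and `cutpoint`.
#' @export
dichotomize_expression <- function(study, gene_id, rule = c("median", "maxstat"),
                                   sample_ids = NULL) {
  rule <- match.arg(rule)
  if (is.null(sample_ids)) {
    sample_ids <- study$samples$sample_id[study$samples$group != "CTR"]
  }
  x <- study$matrix[match(gene_id, study$genes$gene_id), sample_ids]
  if (anyNA(x)) stop("unknown gene or sample id")
  if (stats::sd(x) == 0) stop("constant expression for ", gene_id)
  if (rule == "median") {
    cut <- stats::median(x)
  } else {
    qs <- stats::quantile(x, c(0.1, 0.9))
    cand <- sort(unique(x))
    cand <- cand[cand >= qs[1] & cand <= qs[2]]
    meta <- study$samples[match(sample_ids, study$samples$sample_id), ]
    ok <- !is.na(meta$os_months) & !is.na(meta$os_event)
    best <- -Inf; cut <- stats::median(x)
    for (cc in cand) {
      lo <- x <= cc
      if (!any(lo[ok]) || all(lo[ok])) next
      lr <- logrank_test(meta$os_months[ok & lo], meta$os_event[ok & lo],
                         meta$os_months[ok & !lo], meta$os_event[ok & !lo])
      if (lr$chi2 > best) { best <- lr$chi2; cut <- cc }
    }
  }
  list(low = sample_ids[x <= cut], high = sample_ids[x > cut], cutpoint = cut)
}

# Efron-tie Cox partial likelihood, gradient and information at beta
cox_loglik <- function(x, time, event, beta) {
  eta <- as.numeric(x %*% beta)
  theta <- exp(eta)
  p <- ncol(x)
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (t in sort(unique(time[event]))) {
    r_set <- which(time >= t)
    d_set <- which(time == t & event)
    d <- length(d_set)
    s0 <- sum(theta[r_set])
    s1 <- colSums(theta[r_set] * x[r_set, , drop = FALSE])
    s2 <- crossprod(x[r_set, , drop = FALSE] * sqrt(theta[r_set]))
    s0d <- sum(theta[d_set])
    s1d <- colSums(theta[d_set] * x[d_set, , drop = FALSE])
    s2d <- crossprod(x[d_set, , drop = FALSE] * sqrt(theta[d_set]))
    ll <- ll + sum(eta[d_set])
    grad <- grad + colSums(x[d_set, , drop = FALSE])
    for (l in seq_len(d) - 1L) {
      phi <- l / d
      s0l <- s0 - phi * s0d
      s1l <- s1 - phi * s1d
      s2l <- s2 - phi * s2d
      ll <- ll - log(s0l)
      grad <- grad - s1l / s0l
      info <- info + s2l / s0l - tcrossprod(s1l / s0l)
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

#' Cox proportional hazards fit (Efron ties, Newton-Raphson)
#'
#' Maximizes the Efron-tie partial likelihood by Newton-Raphson from
#' `beta = 0`, declaring convergence when the largest score component falls
#' below `1e-8` (or after 50 iterations). Wald confidence limits are
#' `exp(beta +/- 1.96 se)`. Monotone-likelihood separation (a coefficient
#' running away) raises an error naming the variable.
#'
#' @param records data.frame from [survival_records()] (or any frame with
#'   `time`, `event` and covariate columns).
#' @param variables covariate column names to fit.
#' @return a `CoxModel` list: `variables`, `beta`, `se`, `HR`, `ci95_low`,
#'   `ci95_high`, `wald_p`, `n`, `n_events`, `log_partial_likelihood`,
#'   `iterations`.
#' @export
cox_fit <- function(records, variables) {
  stopifnot(all(c("time", "event") %in% colnames(records)),
            all(variables %in% colnames(records)))
  if (!length(variables)) stop("no covariates to fit")
  x <- as.matrix(records[, variables, drop = FALSE])
  storage.mode(x) <- "double"
  time <- records$time
  event <- as.logical(records$event)
  if (sum(event) < length(variables) + 1) {
    stop("too few events (", sum(event), ") for ", length(variables),
         " covariate(s)")
  }
  beta <- numeric(ncol(x))
  it <- 0L
  repeat {
    it <- it + 1L
    state <- cox_loglik(x, time, event, beta)
    if (max(abs(state$grad)) < 1e-8 || it > 50L) break
    step <- tryCatch(solve(state$info, state$grad), error = function(e) NULL)
    if (is.null(step)) stop("singular information matrix; variables: ",
                            paste(variables, collapse = ", "))
    beta <- beta + step
    if (any(abs(beta) > 20)) {
      stop("monotone likelihood (separation) for variable ",
           variables[which.max(abs(beta))])
    }
  }
  if (it > 50L && max(abs(state$grad)) > 1e-6) {
    stop("Cox fit did not converge; variables: ",
         paste(variables, collapse = ", "))
  }
  beta <- as.numeric(beta)
  se <- as.numeric(sqrt(diag(solve(state$info))))
  z <- beta / se
  structure(list(variables = variables, beta = beta, se = se,
                 HR = exp(beta),
                 ci95_low = exp(beta - 1.96 * se),
                 ci95_high = exp(beta + 1.96 * se),
                 wald_p = 2 * stats::pnorm(-abs(z)),
                 n = nrow(records), n_events = sum(event),
                 log_partial_likelihood = state$loglik,
                 iterations = it),
            class = "CoxModel")
}

#' @export
print.CoxModel <- function(x, ...) {
  if (!length(x$variables)) {
    cat("CoxModel: empty model (no retained variables)\n")
    return(invisible(x))
  }
  tab <- data.frame(variable = x$variables, HR = round(x$HR, 3),
                    ci95 = sprintf("%.3f-%.3f", x$ci95_low, x$ci95_high),
                    p = signif(x$wald_p, 3))
  cat("CoxModel on", x$n, "records /", x$n_events, "events\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Backward variable selection on a Cox model
#'
#' Fits the full model, then iteratively removes the variable with the
#' largest Wald p above `alpha_stay` (p-ties broken by dropping the later
#' input position first) and refits, until every remaining variable has
#' `p <= alpha_stay`. Returns the final model with its variables sorted by
#' descending p, plus the ordered removal trace. If everything is removed an
#' empty model is returned with a warning. A variable causing monotone
#' likelihood (separation, e.g. a rare mutation flag with no events in one
#' stratum) is eliminated with a warning and `p = NA` in the trace.
#'
#' @param records data.frame with `time`, `event` and covariates.
#' @param variables starting covariate set, in input order.
#' @param alpha_stay retention threshold on the Wald p (default 0.05).
#' @return list with `model` (a `CoxModel`, or empty-model stub) and
#'   `removal_trace` (data.frame variable, p, step).
#' @export
backward_select <- function(records, variables, alpha_stay = 0.05) {
  current <- variables
  trace <- data.frame(variable = character(0), p = numeric(0),
                      step = integer(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (!length(current)) {
      warning("backward selection removed every variable")
      empty <- structure(list(variables = character(0), beta = numeric(0),
                              se = numeric(0), HR = numeric(0),
                              ci95_low = numeric(0), ci95_high = numeric(0),
                              wald_p = numeric(0), n = nrow(records),
                              n_events = sum(records$event),
                              log_partial_likelihood = NA_real_,
                              iterations = 0L), class = "CoxModel")
      return(list(model = empty, removal_trace = trace))
    }
    fit <- tryCatch(cox_fit(records, current), error = function(e) e)
    if (inherits(fit, "error")) {
      # monotone likelihood: eliminate the runaway variable and continue
      hit <- regmatches(conditionMessage(fit),
                        regexec("separation\\) for variable (\\S+)",
                                conditionMessage(fit)))[[1]]
      if (length(hit) < 2) stop(fit)
      warning("dropping ", hit[2], " (monotone likelihood)")
      step <- step + 1L
      trace <- rbind(trace, data.frame(variable = hit[2], p = NA_real_,
                                       step = step, stringsAsFactors = FALSE))
      current <- setdiff(current, hit[2])
      next
    }
    worst <- which(fit$wald_p == max(fit$wald_p))
    worst <- worst[length(worst)]  # tie: drop the later input position
    if (fit$wald_p[worst] <= alpha_stay) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(variable = current[worst],
                                     p = fit$wald_p[worst], step = step,
                                     stringsAsFactors = FALSE))
    current <- current[-worst]
  }
  ord <- order(-fit$wald_p)
  fit$variables <- fit$variables[ord]
  fit$beta <- fit$beta[ord]; fit$se <- fit$se[ord]
  fit$HR <- fit$HR[ord]
  fit$ci95_low <- fit$ci95_low[ord]; fit$ci95_high <- fit$ci95_high[ord]
  fit$wald_p <- fit$wald_p[ord]
  list(model = fit, removal_trace = trace)
}

significance_stars <- function(p) {
  ifelse(p < 1e-4, "****", ifelse(p < 1e-3, "***",
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s."))))
}

#' Univariate forest table for an endpoint
#'
#' Each variable is assessed alone: a one-covariate Cox fit on the continuous
#' (expression-standardized) value gives the hazard ratio with its Wald CI,
#' and a log-rank test on the median-dichotomized variable (binary variables
#' used as-is) gives the plotted p. Stars follow the 0.05/0.01/0.001/0.0001
#' convention. Rows keep the input variable order.
#'
#' @param study an `ExpressionStudy`.
#' @param variables covariate names (see [get_covariate()]).
#' @param endpoint `"os"` or `"pfs"`.
#' @return data.frame: `variable`, `HR`, `ci95_low`, `ci95_high`, `cox_p`,
#'   `logrank_p`, `stars`, `n`.
#' @export
univariate_forest <- function(study, variables, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  rows <- lapply(variables, function(v) {
    rec <- suppressMessages(survival_records(study, endpoint, v))
    fit <- tryCatch(cox_fit(rec, v), error = function(e) NULL)
    x <- rec[[v]]
    binary <- length(unique(x)) == 2
    cut <- if (binary) min(x) else stats::median(x)
    lo <- x <= cut
    lr <- if (any(lo) && any(!lo)) {
      logrank_test(rec$time[lo], rec$event[lo], rec$time[!lo], rec$event[!lo])
    } else list(p = NA_real_)
    data.frame(variable = v,
               HR = if (is.null(fit)) NA_real_ else fit$HR,
               ci95_low = if (is.null(fit)) NA_real_ else fit$ci95_low,
               ci95_high = if (is.null(fit)) NA_real_ else fit$ci95_high,
               cox_p = if (is.null(fit)) NA_real_ else fit$wald_p,
               logrank_p = lr$p,
               stars = significance_stars(lr$p),
               n = nrow(rec), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Spearman correlation matrix over covariates
#'
#' Average-rank Spearman r on pairwise-complete observations; p from the t
#' approximation on n - 2 df. Cells with fewer than `min_pairs` complete
#' pairs are left missing with a warning.
#'
#' @param study an `ExpressionStudy`.
#' @param variables covariate names (see [get_covariate()]).
#' @param sample_ids samples to use (default: all patients).
#' @param min_pairs minimum complete pairs per cell (default 4).
#' @return list of matrices `r`, `p`, `n`.
#' @export
spearman_matrix <- function(study, variables, sample_ids = NULL, min_pairs = 4) {
  if (is.null(sample_ids)) {
    sample_ids <- study$samples$sample_id[study$samples$group != "CTR"]
  }
  idx <- match(sample_ids, study$samples$sample_id)
  vals <- vapply(variables, function(v) get_covariate(study, v)[idx],
                 numeric(length(idx)))
  k <- length(variables)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(vals[, c(i, j)])
    n[i, j] <- sum(ok)
    if (sum(ok) < min_pairs) {
      if (i < j) warning("fewer than ", min_pairs, " complete pairs for ",
                         variables[i], " vs ", variables[j])
      next
    }
    rij <- spearman_rp(vals[ok, i], vals[ok, j])
    r[i, j] <- rij$r
    p[i, j] <- rij$p
  }
  list(r = r, p = p, n = n)
}

# average-rank Spearman with t-approximation p (n - 2 df)
spearman_rp <- function(x, y) {
  n <- length(x)
  r <- stats::cor(rank(x), rank(y))
  if (is.na(r) || abs(r) >= 1 || n < 3) {
    p <- if (is.na(r)) NA_real_ else 0
    if (!is.na(r) && abs(r) < 1) p <- 1
    return(list(r = r, p = p))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Lower/intermediate-risk (IPSS-R < 4.5) Cox sub-analysis
#'
#' Restricts the cohort to patients with IPSS-R score below 4.5 and reruns
#' backward-selected Cox models for both endpoints.
#'
#' @param study an `ExpressionStudy`.
#' @param variables starting covariate set.
#' @param alpha_stay retention threshold (default 0.05).
#' @return list with `os` and `pfs` (each a [backward_select()] result) and
#'   `n_selected`.
#' @export
lower_risk_subanalysis <- function(study, variables, alpha_stay = 0.05) {
  sel <- !is.na(study$samples$ipssr_score) & study$samples$ipssr_score < 4.5 &
    study$samples$group != "CTR"
  if (!any(sel)) stop("no patients with IPSS-R score below 4.5")
  if (sum(sel) < 10) warning("only ", sum(sel), " eligible patients")
  sub <- subset_study(study, sample_ids = study$samples$sample_id[sel])
  res <- lapply(c(os = "os", pfs = "pfs"), function(ep) {
    rec <- survival_records(sub, ep, variables)
    backward_select(rec, variables, alpha_stay)
  })
  c(res, list(n_selected = sum(sel)))
}
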