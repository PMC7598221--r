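#' Simulation configuration with study-scale defaults
#'
#' Defaults emulate a CD34+ bone marrow profiling cohort: ~10^4 lncRNA and
#' ~10^4 PCG features over 77 samples split into the eight WHO-style groups
#' (9 controls, 54 MDS across six subtypes, 14 AML-MRC), planted group
#' effects of |logFC| 2, three planted coexpression modules spanning both
#' biotypes, mutation-linked expression shifts for the five recurrently
#' mutated genes, and survival hazards driven by designated marker genes.
#'
#' @param n_lnc,n_pcg numbers of lncRNA and PCG features.
#' @param n_samples_per_group named integer vector, group label -> sample
#'   count; names must be a subset of [study_groups()].
#' @param n_modules number of planted coexpression modules.
#' @param module_size_lnc,module_size_pcg members per module by biotype.
#' @param module_factor_sd SD of the per-sample module factor scores.
#' @param de_fraction fraction of genes planted as differentially expressed in
#'   each patient group versus controls.
#' @param de_logfc planted absolute log2 fold change.
#' @param noise_sd residual log2 SD.
#' @param survival_beta named numeric, marker gene -> log hazard per SD of
#'   expression.
#' @param baseline_hazard exponential baseline hazard per month.
#' @param censor_rate target fraction of censored patients in `[0, 1)`.
#' @param n_terms number of annotation terms to simulate.
#' @param term_enrichment fraction of each planted module covered by its
#'   matched term.
#' @param mutation_carriers named integer vector, gene symbol -> number of
#'   carriers planted among screened patients.
#' @param mutation_de_genes,mutation_logfc number of genes shifted in carriers
#'   of each mutation, and the shift in log2 units.
#' @param n_unscreened_patients,n_unscreened_controls samples left without a
#'   mutational screen (no mutation record at all).
#' @param include_anchors plant the named locus genes (H19, WT1-AS, LEF1-AS1,
#'   TCL6, IGF2, WT1, LEF1, miR-675) with risk-graded effects, shared cis
#'   latent factors and a discordant higher-risk subset; requires
#'   `n_lnc >= 4` and `n_pcg >= 3`.
#' @param discordant_fraction fraction of advanced-disease patients whose
#'   H19/IGF2/miR-675 coregulation is disrupted (H19 shifted by
#'   `discordant_shift` log2 units).
#' @param discordant_shift log2 shift applied to H19 in discordant samples.
#' @param seed integer RNG seed.
#' @return a validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_lnc = 10000, n_pcg = 10000,
                              n_samples_per_group = c(
                                "CTR" = 9, "MDS-SLD" = 6, "MDS-MLD" = 12,
                                "MDS-RS" = 8, "MDS-del5q" = 8, "MDS-EB1" = 10,
                                "MDS-EB2" = 10, "AML-MRC" = 14),
                              n_modules = 3,
                              module_size_lnc = 15, module_size_pcg = 40,
                              module_factor_sd = 1,
                              de_fraction = 0.02, de_logfc = 2,
                              noise_sd = 0.5,
                              survival_beta = c(H19 = 0.7),
                              baseline_hazard = 0.03, censor_rate = 0.3,
                              n_terms = 50, term_enrichment = 0.8,
                              mutation_carriers = c(SF3B1 = 14, TET2 = 10,
                                                    TP53 = 10, DNMT3A = 9,
                                                    RUNX1 = 9),
                              mutation_de_genes = 20, mutation_logfc = 0.5,
                              n_unscreened_patients = 4,
                              n_unscreened_controls = 1,
                              include_anchors = TRUE,
                              discordant_fraction = 0.25,
                              discordant_shift = 4.5,
                              seed = 1L) {
  cfg <- list(n_lnc = n_lnc, n_pcg = n_pcg,
              n_samples_per_group = n_samples_per_group,
              n_modules = n_modules, module_size_lnc = module_size_lnc,
              module_size_pcg = module_size_pcg,
              module_factor_sd = module_factor_sd,
              de_fraction = de_fraction, de_logfc = de_logfc,
              noise_sd = noise_sd, survival_beta = survival_beta,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              n_terms = n_terms, term_enrichment = term_enrichment,
              mutation_carriers = mutation_carriers,
              mutation_de_genes = mutation_de_genes,
              mutation_logfc = mutation_logfc,
              n_unscreened_patients = n_unscreened_patients,
              n_unscreened_controls = n_unscreened_controls,
              include_anchors = include_anchors,
              discordant_fraction = discordant_fraction,
              discordant_shift = discordant_shift,
              seed = as.integer(seed))
  stopifnot(n_lnc >= 1, n_pcg >= 1, n_modules >= 1,
            module_factor_sd > 0, noise_sd > 0, baseline_hazard > 0,
            censor_rate >= 0, censor_rate < 1,
            de_fraction >= 0, de_fraction <= 1,
            term_enrichment > 0, term_enrichment <= 1)
  if (is.null(names(n_samples_per_group)) ||
      !all(names(n_samples_per_group) %in% study_groups())) {
    stop("n_samples_per_group must be named with known group labels")
  }
  if (n_modules * module_size_lnc > n_lnc ||
      n_modules * module_size_pcg > n_pcg) {
    stop("module sizes exceed available genes per biotype")
  }
  if (include_anchors && (n_lnc < 4 || n_pcg < 3)) {
    stop("anchor genes need n_lnc >= 4 and n_pcg >= 3")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

# disease-severity gradient used for anchor-gene effects and IPSS-R scores
severity_scale <- function() c(
  "CTR" = 0, "MDS-SLD" = 0.15, "MDS-MLD" = 0.35, "MDS-RS" = 0.35,
  "MDS-del5q" = 0.35, "MDS-EB1" = 0.55, "MDS-EB2" = 0.8, "AML-MRC" = 1)

ipssr_category_of <- function(score) {
  ifelse(is.na(score), NA_character_,
  ifelse(score <= 1.5, "very_low",
  ifelse(score <= 3, "low",
  ifelse(score <= 4.5, "intermediate",
  ifelse(score <= 6, "high", "very_high")))))
}

#' Simulate an expression study with planted ground truth
#'
#' Generates `x_gs = mu_g + sum_c delta_gc I[s in c] + sum_m lambda_gm f_ms +
#' eps_gs` with module factor scores `f_ms ~ N(0, module_factor_sd)` and
#' residual noise `eps ~ N(0, noise_sd)`. Planted structure: per-group DE
#' genes versus controls, coexpression modules spanning both biotypes (all
#' module members are also planted DE so they enter a DE-restricted network),
#' mutation-carrier expression shifts, risk-graded anchor genes with shared
#' cis factors, and a discordant H19 subset in advanced disease. All draws
#' derive from `config$seed`; the same config reproduces the matrix exactly.
#'
#' @param config a [simulation_config()].
#' @return list with elements `study` (an `ExpressionStudy`) and `truth`
#'   (a `GroundTruth` list recording every planted feature).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  groups <- rep(names(config$n_samples_per_group), config$n_samples_per_group)
  n_s <- length(groups)
  sample_ids <- sprintf("S%03d", seq_len(n_s))
  sev <- severity_scale()[groups]

  lnc_ids <- sprintf("LNC%05d", seq_len(config$n_lnc))
  pcg_ids <- sprintf("PCG%05d", seq_len(config$n_pcg))
  anchors <- NULL
  if (config$include_anchors) {
    lnc_ids[1:4] <- c("H19", "WT1-AS", "LEF1-AS1", "TCL6")
    pcg_ids[1:3] <- c("IGF2", "WT1", "LEF1")
    anchors <- c("H19", "WT1-AS", "LEF1-AS1", "TCL6", "IGF2", "WT1", "LEF1",
                 "miR-675")
  }
  gene_ids <- c(lnc_ids, pcg_ids, if (config$include_anchors) "miR-675")
  biotype <- c(rep("lncRNA", config$n_lnc), rep("PCG", config$n_pcg),
               if (config$include_anchors) "miRNA")
  partner <- rep(NA_character_, length(gene_ids))
  if (config$include_anchors) {
    names(partner) <- gene_ids
    partner[c("WT1-AS", "LEF1-AS1", "H19", "miR-675")] <-
      c("WT1", "LEF1", "IGF2", "H19")
    partner <- unname(partner)
  }
  n_g <- length(gene_ids)

  mu <- stats::rnorm(n_g, mean = 7, sd = 1.5)
  x <- matrix(rep(mu, n_s), nrow = n_g)
  rownames(x) <- gene_ids
  colnames(x) <- sample_ids

  # planted per-group DE versus controls
  patient_groups <- setdiff(unique(groups), "CTR")
  n_de <- floor(config$de_fraction * n_g)
  plain <- setdiff(gene_ids, anchors)
  de_truth <- list()
  for (g in patient_groups) {
    ids <- sample(plain, n_de)
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    lfc <- sgn * config$de_logfc
    x[match(ids, gene_ids), groups == g] <-
      x[match(ids, gene_ids), groups == g] + lfc
    de_truth[[g]] <- data.frame(gene_id = ids, logfc = lfc,
                                stringsAsFactors = FALSE)
  }

  # planted coexpression modules: members drawn from non-anchor, non-DE genes,
  # up-shifted in every patient group (hence DE vs CTR) + shared latent factor
  pool_lnc <- setdiff(lnc_ids, c(anchors, unlist(lapply(de_truth, `[[`, "gene_id"))))
  pool_pcg <- setdiff(pcg_ids, c(anchors, unlist(lapply(de_truth, `[[`, "gene_id"))))
  module_members <- list()
  f <- matrix(stats::rnorm(n_s * config$n_modules, 0, config$module_factor_sd),
              nrow = n_s,
              dimnames = list(sample_ids, sprintf("M%d", seq_len(config$n_modules))))
  for (m in seq_len(config$n_modules)) {
    mem_l <- sample(pool_lnc, config$module_size_lnc)
    pool_lnc <- setdiff(pool_lnc, mem_l)
    mem_p <- sample(pool_pcg, config$module_size_pcg)
    pool_pcg <- setdiff(pool_pcg, mem_p)
    mem <- c(mem_l, mem_p)
    module_members[[sprintf("M%d", m)]] <- mem
    idx <- match(mem, gene_ids)
    x[idx, ] <- x[idx, ] + matrix(rep(f[, m], each = length(mem)),
                                  nrow = length(mem))
    x[idx, groups != "CTR"] <- x[idx, groups != "CTR"] + config$de_logfc
  }

  # mutation assignment among screened patients + carrier expression shifts
  patients <- which(groups != "CTR")
  controls <- which(groups == "CTR")
  unscreened <- c(
    if (config$n_unscreened_patients > 0)
      sample(patients, min(config$n_unscreened_patients, length(patients))),
    if (config$n_unscreened_controls > 0)
      sample(controls, min(config$n_unscreened_controls, length(controls))))
  screened <- setdiff(seq_len(n_s), unscreened)
  screened_patients <- intersect(screened, patients)
  mutations <- replicate(n_s, stats::setNames(numeric(0), character(0)),
                         simplify = FALSE)
  carriers <- list()
  mut_de <- list()
  mut_pool <- setdiff(plain, unlist(module_members))
  for (sym in names(config$mutation_carriers)) {
    k <- config$mutation_carriers[[sym]]
    if (k > length(screened_patients)) {
      stop("more ", sym, " carriers requested than screened patients")
    }
    ids <- sample(screened_patients, k)
    carriers[[sym]] <- sample_ids[sort(ids)]
    for (i in ids) {
      vaf <- stats::runif(1, 0.1, 0.5)
      mutations[[i]] <- c(mutations[[i]], stats::setNames(vaf, sym))
    }
    if (config$mutation_de_genes > 0) {
      eff <- sample(mut_pool, min(config$mutation_de_genes, length(mut_pool)))
      mut_pool <- setdiff(mut_pool, eff)
      sgn <- sample(c(-1, 1), length(eff), replace = TRUE)
      x[match(eff, gene_ids), ids] <- x[match(eff, gene_ids), ids] +
        matrix(rep(sgn * config$mutation_logfc, length(ids)), ncol = length(ids))
      mut_de[[sym]] <- data.frame(gene_id = eff,
                                  logfc = sgn * config$mutation_logfc,
                                  stringsAsFactors = FALSE)
    }
  }

  # anchor genes: risk-graded effects, shared cis factors, discordant subset
  discordant <- character(0)
  if (config$include_anchors) {
    add <- function(gene, delta) {
      x[match(gene, gene_ids), ] <<- x[match(gene, gene_ids), ] + delta
    }
    add("H19", 2.5 * sev)
    add("WT1-AS", 2 * sev)
    add("LEF1-AS1", -2 * sev)
    add("TCL6", -2 * sev)
    add("IGF2", -1.5 * sev)
    add("miR-675", -1.5 * sev)
    for (pair in list(c("WT1", "WT1-AS"), c("LEF1", "LEF1-AS1"),
                      c("H19", "IGF2", "miR-675"))) {
      u <- stats::rnorm(n_s)
      for (g in pair) add(g, u)
    }
    advanced <- which(groups %in% c("MDS-EB1", "MDS-EB2", "AML-MRC"))
    n_disc <- round(config$discordant_fraction * length(advanced))
    if (n_disc > 0) {
      disc_idx <- sample(advanced, n_disc)
      x[match("H19", gene_ids), disc_idx] <-
        x[match("H19", gene_ids), disc_idx] + config$discordant_shift
      discordant <- sample_ids[sort(disc_idx)]
    }
  }

  x <- x + matrix(stats::rnorm(n_g * n_s, 0, config$noise_sd), nrow = n_g)

  # clinical covariates
  score <- rep(NA_real_, n_s)
  rng <- list("MDS-SLD" = c(0.5, 3), "MDS-MLD" = c(1, 4.5), "MDS-RS" = c(1, 4.5),
              "MDS-del5q" = c(1, 4.5), "MDS-EB1" = c(3, 6), "MDS-EB2" = c(4.5, 9))
  for (g in names(rng)) {
    i <- groups == g
    score[i] <- round(stats::runif(sum(i), rng[[g]][1], rng[[g]][2]) * 2) / 2
  }
  blast_rng <- list("CTR" = c(0, 2), "MDS-SLD" = c(0, 4), "MDS-MLD" = c(0, 4),
                    "MDS-RS" = c(0, 4), "MDS-del5q" = c(0, 4),
                    "MDS-EB1" = c(5, 9), "MDS-EB2" = c(10, 19),
                    "AML-MRC" = c(20, 60))
  blast <- vapply(seq_len(n_s), function(i)
    stats::runif(1, blast_rng[[groups[i]]][1], blast_rng[[groups[i]]][2]), 0)
  karyo <- ifelse(groups == "MDS-del5q", "isolated_del5q",
                  sample(c("normal", "other"), n_s, TRUE, prob = c(0.7, 0.3)))
  karyo[groups == "CTR"] <- "normal"

  samples <- data.frame(
    sample_id = sample_ids, group = groups,
    ipssr_score = score, ipssr_category = ipssr_category_of(score),
    karyotype = karyo,
    os_months = NA_real_, os_event = NA, pfs_months = NA_real_, pfs_event = NA,
    age = round(stats::rnorm(n_s, 70, 8), 1),
    blast_pct = round(blast, 1),
    hemoglobin = round(stats::rnorm(n_s, ifelse(groups == "CTR", 140, 100), 15), 1),
    neutrophils = round(exp(stats::rnorm(n_s, log(2), 0.5)), 2),
    platelets = round(exp(stats::rnorm(n_s, log(150), 0.6)), 0),
    screened = seq_len(n_s) %in% screened,
    stringsAsFactors = FALSE)
  samples$mutations <- mutations
  samples$mutations[unscreened] <- list(NULL)

  genes <- data.frame(gene_id = gene_ids, biotype = biotype,
                      partner_id = partner, stringsAsFactors = FALSE)
  study <- expression_study(x, genes, samples)
  truth <- structure(list(
    gene_ids = gene_ids, de = de_truth, modules = module_members,
    module_factors = f, mutation_de = mut_de, carriers = carriers,
    discordant_samples = discordant, anchors = anchors,
    config = config), class = "GroundTruth")
  list(study = study, truth = truth)
}

#' Attach simulated survival endpoints to a study
#'
#' Event times are exponential with rate `baseline_hazard *
#' exp(sum_g beta_g z_gs)` where `z` is the marker expression standardized
#' over patients. Censoring is independent uniform on `(0, c_max)` with
#' `c_max` solved numerically so the expected censored fraction matches
#' `censor_rate` (no censoring when `censor_rate = 0`). Progression-free
#' survival uses the same linear predictor with a 1.4x rate, truncated at the
#' OS time. Controls keep missing endpoints.
#'
#' @param study an `ExpressionStudy`.
#' @param config the [simulation_config()] that generated it (supplies
#'   `survival_beta`, `baseline_hazard`, `censor_rate`, `seed`).
#' @return the study with `os_months`/`os_event`/`pfs_months`/`pfs_event`
#'   filled for patients.
#' @export
simulate_survival <- function(study, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  beta <- config$survival_beta
  miss <- setdiff(names(beta), study$genes$gene_id)
  if (length(miss)) stop("unknown marker gene: ", paste(miss, collapse = ", "))
  pat <- study$samples$group != "CTR"
  n_p <- sum(pat)
  lp <- rep(0, n_p)
  for (g in names(beta)) {
    z <- study$matrix[g, pat]
    lp <- lp + beta[[g]] * as.numeric(scale(z))
  }
  rate <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n_p, rate)
  if (config$censor_rate > 0) {
    # fraction censored under C ~ U(0, cmax): mean over samples of
    # P(C < t) = E[min(t/cmax, 1)]
    frac <- function(cmax) mean(pmin(t_event / cmax, 1)) - config$censor_rate
    cmax <- stats::uniroot(frac, c(min(t_event) * 1e-3, max(t_event) * 1e3))$root
    cens <- stats::runif(n_p, 0, cmax)
  } else {
    cens <- rep(Inf, n_p)
  }
  os <- pmin(t_event, cens)
  os_event <- t_event <= cens
  t_prog <- stats::rexp(n_p, 1.4 * rate)
  pfs <- pmin(t_prog, os)
  pfs_event <- (t_prog <= os) | os_event
  study$samples$os_months[pat] <- round(os, 2)
  study$samples$os_event[pat] <- os_event
  study$samples$pfs_months[pat] <- round(pmax(pfs, 0.01), 2)
  study$samples$pfs_event[pat] <- pfs_event
  study
}

#' Simulate term annotations matched to planted modules
#'
#' Each planted module receives a matched term covering `term_enrichment` of
#' its members; the remaining terms are uniform random draws from the gene
#' universe. Emits both a two-column gene-to-term table and a GMT-style list.
#'
#' @param truth a `GroundTruth` from [simulate_study()].
#' @param config the matching [simulation_config()].
#' @return list with `term_table` (data.frame gene_id, term), `gmt` (named
#'   list of member vectors) and `matched_terms` (module id -> term name).
#' @export
simulate_annotation <- function(truth, config) {
  stopifnot(inherits(truth, "GroundTruth"),
            inherits(config, "SimulationConfig"))
  if (!length(truth$modules)) stop("ground truth has no planted modules")
  set.seed(config$seed + 2L)
  universe <- truth$gene_ids
  gmt <- list()
  matched <- character(0)
  for (m in names(truth$modules)) {
    mem <- truth$modules[[m]]
    k <- max(1L, ceiling(config$term_enrichment * length(mem)))
    nm <- paste0("TERM_", m)
    gmt[[nm]] <- sort(sample(mem, k))
    matched[m] <- nm
  }
  n_bg <- max(0L, config$n_terms - length(gmt))
  for (i in seq_len(n_bg)) {
    sz <- sample(10:50, 1)
    gmt[[sprintf("TERM_BG%03d", i)]] <- sort(sample(universe, min(sz, length(universe))))
  }
  term_table <- do.call(rbind, lapply(names(gmt), function(nm)
    data.frame(gene_id = gmt[[nm]], term = nm, stringsAsFactors = FALSE)))
  rownames(term_table) <- NULL
  list(term_table = term_table, gmt = gmt, matched_terms = matched)
}
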