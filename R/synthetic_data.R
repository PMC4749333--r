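#' Configuration for the synthetic Cq data generator
#'
#' Defines a simulated reference-gene study patterned on a 25-gene, 20-sample
#' plant qPCR survey: nine genotype samples, eight abiotic-stress samples and
#' five tissue samples sharing one common control, each sample with three
#' biological and three technical replicates. Expression noise is injected
#' on the log2 scale, where stability methods measure dispersion, and
#' converted to cycles through each gene's amplification efficiency.
#'
#' @param n_genes number of candidate genes (default 25).
#' @param design data frame describing the samples (columns `sample_id`,
#'   `set_memberships`, `group`, `is_control`); default [default_design()].
#' @param n_bio_reps biological replicates per sample (default 3).
#' @param n_tech_reps technical replicates per biological replicate
#'   (default 3).
#' @param baseline_cq per-gene baseline Cq (cycles); default drawn uniformly
#'   in 19-28, the typical mid-abundance window of candidate panels.
#' @param efficiency per-gene amplification efficiency fractions; default
#'   drawn uniformly in 0.90-1.09, the usual validated-primer range.
#' @param tau per-gene expression noise SD (log2 units), the ground-truth
#'   instability; default ascending from 0.02 to 0.8 across genes.
#' @param group_effects optional gene x group matrix of log2 expression
#'   shifts for stress/tissue contrasts (default none).
#' @param sample_effect_sd SD (log2) of the per-sample loading effect shared
#'   by all genes (default 0.5); cancels in ratio-based statistics.
#' @param tech_sd technical replicate SD in cycles (default 0.15).
#' @param seed integer seed; required.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 25,
                              design = default_design(),
                              n_bio_reps = 3,
                              n_tech_reps = 3,
                              baseline_cq = NULL,
                              efficiency = NULL,
                              tau = NULL,
                              group_effects = NULL,
                              sample_effect_sd = 0.5,
                              tech_sd = 0.15,
                              seed) {
  assert_that(!missing(seed) && is.finite(seed), "`seed` is required")
  assert_that(n_genes >= 3L, "need at least 3 genes")
  assert_that(n_bio_reps >= 1L && n_tech_reps >= 1L, "replicate counts must be >= 1")
  assert_that(sample_effect_sd >= 0 && tech_sd >= 0, "SDs must be non-negative")
  if (!is.null(tau)) assert_that(all(tau >= 0), "tau must be non-negative")
  cfg <- list(n_genes = as.integer(n_genes), design = design,
              n_bio_reps = as.integer(n_bio_reps), n_tech_reps = as.integer(n_tech_reps),
              baseline_cq = baseline_cq, efficiency = efficiency, tau = tau,
              group_effects = group_effects,
              sample_effect_sd = sample_effect_sd, tech_sd = tech_sd,
              seed = as.integer(seed))
  structure(cfg, class = "simulation_config")
}

#' Default 20-sample study design
#'
#' Nine genotypes (the first doubling as the common control shared by every
#' set), eight stress-set samples (six treatments plus two controls), and
#' five tissues; 20 unique samples, each a member of the `all` set.
#'
#' @return Data frame with columns `sample_id`, `set_memberships`, `group`,
#'   `is_control`.
#' @export
default_design <- function() {
  rbind(
    data.frame(sample_id = "JG11",
               set_memberships = "genotypes;stress;tissues;all",
               group = "control", is_control = TRUE),
    data.frame(sample_id = paste0("genotype", 2:9),
               set_memberships = "genotypes;all",
               group = "genotype", is_control = FALSE),
    data.frame(sample_id = c("drought", "salt", "vpd", "aba", "cold", "heat"),
               set_memberships = "stress;all",
               group = "stressed", is_control = FALSE),
    data.frame(sample_id = "drought_ctrl",
               set_memberships = "stress;all",
               group = "control", is_control = TRUE),
    data.frame(sample_id = c("root", "flower", "seedling", "seed"),
               set_memberships = "tissues;all",
               group = c("root", "flower", "seedling", "seed"),
               is_control = FALSE))
}

#' Simulate a Cq dataset with known ground truth
#'
#' The log2 expression of gene j in biological replicate i is
#' `x_ij = beta[group(i), j] + s_i + eps_ij` with `eps_ij ~ N(0, tau_j^2)`
#' and a shared loading effect `s_i ~ N(0, sample_effect_sd^2)`; the
#' corresponding Cq is `a_j - x_ij / log2(1 + E_j)`, and technical
#' replicates add `N(0, tech_sd^2)` cycles. With all noise terms zero the
#' dataset is perfectly stable and every stability statistic is exactly 0.
#'
#' @param cfg a [simulation_config()].
#' @return List with `dataset` (a [cq_dataset()]), `truth` (per-gene `tau`,
#'   `efficiency`, `baseline_cq`, and the condition-level
#'   `log2_expression` gene x sample matrix), and `efficiency` (named
#'   vector, convenience copy).
#' @export
simulate_cq_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  genes <- sprintf("gene%02d", seq_len(cfg$n_genes))
  design <- cfg$design
  samples <- design$sample_id

  a <- cfg$baseline_cq %||% stats::runif(cfg$n_genes, 19, 28)
  e <- cfg$efficiency %||% stats::runif(cfg$n_genes, 0.90, 1.09)
  tau <- cfg$tau %||% seq(0.02, 0.8, length.out = cfg$n_genes)
  assert_that(length(a) == cfg$n_genes && length(e) == cfg$n_genes &&
                length(tau) == cfg$n_genes,
              "baseline_cq, efficiency, tau must have length n_genes")
  names(a) <- names(e) <- names(tau) <- genes

  beta <- matrix(0, cfg$n_genes, nrow(design), dimnames = list(genes, samples))
  if (!is.null(cfg$group_effects)) {
    ge <- cfg$group_effects
    for (s in seq_along(samples)) {
      grp <- design$group[s]
      if (grp %in% colnames(ge)) beta[, s] <- ge[, grp]
    }
  }

  n_units <- nrow(design) * cfg$n_bio_reps
  cq <- array(NA_real_, dim = c(cfg$n_genes, n_units, cfg$n_tech_reps))
  unit_ids <- character(n_units)
  sheet <- design[rep(seq_len(nrow(design)), each = cfg$n_bio_reps), ]
  sheet$bio_rep <- rep(seq_len(cfg$n_bio_reps), times = nrow(design))
  rownames(sheet) <- NULL

  w <- log2(1 + e)  # cycles per log2 expression unit, per gene
  for (u in seq_len(n_units)) {
    s_idx <- match(sheet$sample_id[u], samples)
    s_i <- stats::rnorm(1, 0, cfg$sample_effect_sd)
    eps <- stats::rnorm(cfg$n_genes, 0, tau)
    x <- beta[, s_idx] + s_i + eps
    cq_unit <- a - x / w
    for (t in seq_len(cfg$n_tech_reps)) {
      cq[, u, t] <- cq_unit + stats::rnorm(cfg$n_genes, 0, cfg$tech_sd)
    }
    unit_ids[u] <- paste0(sheet$sample_id[u], "__", sheet$bio_rep[u])
  }
  dimnames(cq) <- list(genes, unit_ids, NULL)

  dataset <- cq_dataset(cq, sheet)
  truth <- list(tau = tau, efficiency = e, baseline_cq = a,
                log2_expression = beta, seed = cfg$seed)
  list(dataset = dataset, truth = truth, efficiency = e)
}

#' Simulate a dilution-series calibration experiment
#'
#' Generates mean Cq values for an n-point serial dilution of a template
#' with true amplification efficiency `E_true`: an exact line of slope
#' `-1/log10(1 + E_true)` against log10 template amount, plus optional
#' Gaussian cycle noise.
#'
#' @param E_true true efficiency fraction (> 0).
#' @param n_points number of dilution points (default 5).
#' @param step fold dilution per point (default 2).
#' @param noise_sd Cq noise SD in cycles (default 0).
#' @param seed optional integer seed (required when `noise_sd > 0`).
#' @param intercept Cq of the undiluted point (default 22).
#' @param gene optional gene label.
#' @return A `dilution_series`: list with `gene`, `dilution_factors`, `cq`,
#'   and the generating `E_true`.
#' @export
simulate_dilution_series <- function(E_true, n_points = 5, step = 2,
                                     noise_sd = 0, seed = NULL,
                                     intercept = 22, gene = NA_character_) {
  assert_that(E_true > 0, "E_true must be positive")
  assert_that(n_points >= 3L, "need at least 3 dilution points")
  assert_that(step > 1, "dilution step must exceed 1")
  d <- step^(-(seq_len(n_points) - 1))
  slope <- -1 / log10(1 + E_true)
  cq <- intercept + slope * log10(d)
  if (noise_sd > 0) {
    assert_that(!is.null(seed), "`seed` is required when noise_sd > 0")
    set.seed(as.integer(seed))
    cq <- cq + stats::rnorm(n_points, 0, noise_sd)
  }
  structure(list(gene = gene, dilution_factors = d, cq = cq, E_true = E_true),
            class = "dilution_series")
}

#' Simulate a reference-gene validation scenario
#'
#' Builds a long-format replicate Cq table for a target gene induced by a
#' known fold change between control and treatment, together with stable
#' reference genes (constant expression) and optionally unstable references
#' whose own expression shifts with treatment — the situation in which
#' normalization against an unstable reference cancels or distorts the true
#' induction.
#'
#' @param fold_change true target fold change (treatment / control, > 0).
#' @param stable_refs number of stable reference genes (default 2).
#' @param unstable_refs number of unstable reference genes (default 2).
#' @param unstable_ref_shift log2 expression shift of the unstable
#'   references under treatment (default 0 = they are stable too).
#' @param reps biological replicates per condition (default 3).
#' @param noise_sd replicate noise SD in log2 expression units (default 0).
#' @param efficiency single efficiency applied to every gene (default 1,
#'   perfect doubling) or named vector covering all genes.
#' @param seed integer seed (required when `noise_sd > 0`).
#' @return List with `cq` (long data frame for [expression_ratio()]),
#'   `target`, `stable_refs`, `unstable_refs`, `eff`, and `truth`.
#' @export
simulate_validation_scenario <- function(fold_change, stable_refs = 2,
                                         unstable_refs = 2,
                                         unstable_ref_shift = 0,
                                         reps = 3, noise_sd = 0,
                                         efficiency = 1, seed = NULL) {
  assert_that(fold_change > 0, "fold_change must be positive")
  assert_that(stable_refs >= 1L, "need at least one stable reference")
  if (noise_sd > 0) {
    assert_that(!is.null(seed), "`seed` is required when noise_sd > 0")
    set.seed(as.integer(seed))
  }
  target <- "target"
  s_refs <- if (stable_refs > 0) paste0("stable_ref", seq_len(stable_refs)) else character(0)
  u_refs <- if (unstable_refs > 0) paste0("unstable_ref", seq_len(unstable_refs)) else character(0)
  genes <- c(target, s_refs, u_refs)

  eff <- if (length(efficiency) == 1L && is.null(names(efficiency))) {
    stats::setNames(rep(efficiency, length(genes)), genes)
  } else {
    assert_that(all(genes %in% names(efficiency)), "named efficiency must cover all genes")
    efficiency[genes]
  }
  baseline <- stats::setNames(c(26, rep(22, length(s_refs)), rep(23, length(u_refs))), genes)
  shift <- stats::setNames(c(log2(fold_change), rep(0, length(s_refs)),
                             rep(unstable_ref_shift, length(u_refs))), genes)

  rows <- expand.grid(gene = genes, condition = c("control", "treatment"),
                      replicate = seq_len(reps), stringsAsFactors = FALSE)
  w <- log2(1 + eff[rows$gene])
  x <- ifelse(rows$condition == "treatment", shift[rows$gene], 0)
  if (noise_sd > 0) x <- x + stats::rnorm(nrow(rows), 0, noise_sd)
  rows$cq <- baseline[rows$gene] - x / w

  list(cq = rows, target = target, stable_refs = s_refs, unstable_refs = u_refs,
       eff = eff,
       truth = list(fold_change = fold_change,
                    unstable_ref_shift = unstable_ref_shift,
                    noise_sd = noise_sd))
}

#' Write a simulated study to disk
#'
#' Emits the same CSV formats [read_cq_table()] consumes (wide Cq table and
#' sample sheet), the per-gene efficiency CSV, and the ground truth as a JSON
#' sidecar.
#'
#' @param sim result of [simulate_cq_dataset()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cq = file.path(dir, "cq.csv"),
             sheet = file.path(dir, "sample_sheet.csv"),
             efficiency = file.path(dir, "efficiency.csv"),
             truth = file.path(dir, "truth.json"))
  write_cq_table(sim$dataset, paths[["cq"]], paths[["sheet"]])
  utils::write.csv(data.frame(gene = names(sim$efficiency),
                              efficiency = unname(sim$efficiency)),
                   paths[["efficiency"]], row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  truth$log2_expression <- as.data.frame(truth$log2_expression)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
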