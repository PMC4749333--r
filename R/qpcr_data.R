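#' Construct a Cq dataset
#'
#' A `cq_dataset` holds raw quantification cycles for a panel of candidate
#' reference genes measured across samples, keeping the replicate hierarchy
#' explicit: each *sample* (an analysis unit such as a genotype, a stress
#' treatment, or a tissue) may have several biological replicates, and each
#' biological replicate several technical replicates. The pair
#' (sample, biological replicate) is called a *unit*; the Cq array is
#' gene x unit x technical replicate.
#'
#' @param cq numeric array of dimension genes x units x technical replicates.
#'   `dimnames` must name genes (axis 1) and units (axis 2); units are
#'   `"<sample>__<bio_rep>"`. Missing wells are `NA`; all non-missing values
#'   must lie in (0, 50) cycles.
#' @param sample_sheet data frame with one row per unit and columns
#'   `sample_id`, `bio_rep`, `set_memberships` (semicolon-separated subset of
#'   `genotypes;stress;tissues;all`), `group` (e.g. treatment or tissue
#'   label), `is_control` (logical).
#' @return An object of class `cq_dataset` with elements `genes`, `samples`,
#'   `units` (data frame), `cq`, and `sample_sheet`.
#' @examples
#' sim <- simulate_cq_dataset(simulation_config(seed = 1))
#' sim$dataset
#' @export
cq_dataset <- function(cq, sample_sheet) {
  assert_that(is.array(cq) && length(dim(cq)) == 3L,
              "`cq` must be a 3-axis array (gene x unit x tech rep)")
  genes <- dimnames(cq)[[1]]
  unit_ids <- dimnames(cq)[[2]]
  assert_that(!is.null(genes) && !is.null(unit_ids),
              "`cq` must carry gene and unit dimnames")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(unit_ids)) stop("duplicate unit identifiers", call. = FALSE)

  bad <- which(!is.na(cq) & (!is.finite(cq) | cq <= 0 | cq >= 50), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("Cq outside (0, 50) at gene '%s', unit '%s', tech rep %d",
                 genes[bad[1, 1]], unit_ids[bad[1, 2]], bad[1, 3]), call. = FALSE)
  }

  req <- c("sample_id", "bio_rep", "set_memberships", "group", "is_control")
  assert_that(all(req %in% names(sample_sheet)),
              paste("sample sheet must have columns:", paste(req, collapse = ", ")))
  sheet <- as.data.frame(sample_sheet)[, req]
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$bio_rep <- as.integer(sheet$bio_rep)
  sheet$group <- as.character(sheet$group)
  sheet$is_control <- as.logical(sheet$is_control)
  sheet$unit_id <- paste0(sheet$sample_id, "__", sheet$bio_rep)
  if (anyDuplicated(sheet$unit_id)) stop("duplicate sample/bio-rep rows in sheet", call. = FALSE)

  unmapped <- setdiff(unit_ids, sheet$unit_id)
  if (length(unmapped) > 0L) {
    stop(sprintf("unmapped column(s) in Cq table: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  sheet <- sheet[match(unit_ids, sheet$unit_id), , drop = FALSE]
  rownames(sheet) <- NULL

  sets <- strsplit(sheet$set_memberships, ";", fixed = TRUE)
  sets <- lapply(sets, function(s) trimws(s[nzchar(trimws(s))]))
  unknown <- setdiff(unlist(sets), SET_LEVELS)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown sample set(s): %s", paste(unique(unknown), collapse = ", ")),
         call. = FALSE)
  }
  assert_that(all(lengths(sets) > 0L), "every sample must belong to at least one set")
  # "all" must contain every sample that is in any other set
  in_other <- vapply(sets, function(s) any(s != "all"), logical(1))
  in_all <- vapply(sets, function(s) "all" %in% s, logical(1))
  assert_that(all(in_all[in_other]),
              "the 'all' set must be a superset of the union of the other sets")

  samples <- unique(sheet$sample_id)
  # per-sample metadata must be replicate-invariant
  per_sample <- unique(sheet[, c("sample_id", "set_memberships", "group", "is_control")])
  assert_that(nrow(per_sample) == length(samples),
              "set/group/control metadata must agree across a sample's biological replicates")

  structure(
    list(genes = genes,
         samples = samples,
         units = sheet[, c("unit_id", "sample_id", "bio_rep")],
         cq = cq,
         sample_sheet = sheet),
    class = "cq_dataset")
}

#' @export
print.cq_dataset <- function(x, ...) {
  cat(sprintf("<cq_dataset> %d genes x %d samples (%d units, %d tech reps)\n",
              length(x$genes), length(x$samples), nrow(x$units), dim(x$cq)[3]))
  sets <- sample_sets(x)
  for (s in names(sets)) cat(sprintf("  set %-9s: %d samples\n", s, length(sets[[s]])))
  invisible(x)
}

#' List the sample sets of a Cq dataset
#'
#' @param d a [cq_dataset()].
#' @return Named list mapping each declared set to its sample identifiers.
#' @export
sample_sets <- function(d) {
  sheet <- unique(d$sample_sheet[, c("sample_id", "set_memberships")])
  sets <- strsplit(sheet$set_memberships, ";", fixed = TRUE)
  out <- lapply(SET_LEVELS, function(s) sheet$sample_id[vapply(sets, function(x) s %in% x, logical(1))])
  names(out) <- SET_LEVELS
  out[lengths(out) > 0L]
}

#' Read a wide Cq table and its sample sheet
#'
#' The Cq file is a wide CSV: one row per gene (first column `gene`), one
#' column per well named `<sample>__<bio_rep>__<tech_rep>`. The sample sheet
#' CSV has one row per (sample, biological replicate) with columns
#' `sample_id`, `bio_rep`, `set_memberships`, `group`, `is_control`. Empty
#' cells become missing values, never zeros.
#'
#' @param path path to the wide Cq CSV.
#' @param sheet_path path to the sample-sheet CSV.
#' @return A [cq_dataset()].
#' @seealso [write_cq_table()] for the inverse operation.
#' @export
read_cq_table <- function(path, sheet_path) {
  assert_that(file.exists(path), sprintf("Cq file not found: %s", path))
  assert_that(file.exists(sheet_path), sprintf("sample sheet not found: %s", sheet_path))
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) stop("no genes parsed", call. = FALSE)
  assert_that(names(tab)[1] == "gene", "first column of the Cq table must be 'gene'")
  genes <- as.character(tab$gene)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers", call. = FALSE)

  wells <- names(tab)[-1]
  parts <- strsplit(wells, "__", fixed = TRUE)
  ok <- lengths(parts) == 3L
  if (!all(ok)) {
    stop(sprintf("column '%s' is not of the form <sample>__<bio_rep>__<tech_rep>",
                 wells[which(!ok)[1]]), call. = FALSE)
  }
  unit_of_well <- vapply(parts, function(p) paste0(p[1], "__", p[2]), character(1))
  tech_of_well <- vapply(parts, function(p) as.integer(p[3]), integer(1))
  units <- unique(unit_of_well)
  n_tech <- max(tech_of_well)

  cq <- array(NA_real_, dim = c(length(genes), length(units), n_tech),
              dimnames = list(genes, units, NULL))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  for (w in seq_along(wells)) {
    cq[, match(unit_of_well[w], units), tech_of_well[w]] <- vals[, w]
  }

  sheet <- utils::read.csv(sheet_path, stringsAsFactors = FALSE)
  cq_dataset(cq, sheet)
}

#' Write a Cq dataset to CSV files
#'
#' @param d a [cq_dataset()].
#' @param path output path for the wide Cq CSV.
#' @param sheet_path output path for the sample-sheet CSV.
#' @return Invisibly, `d`.
#' @export
write_cq_table <- function(d, path, sheet_path) {
  n_tech <- dim(d$cq)[3]
  cols <- list(gene = d$genes)
  for (u in seq_len(nrow(d$units))) {
    for (t in seq_len(n_tech)) {
      cols[[paste0(d$units$unit_id[u], "__", t)]] <- d$cq[, u, t]
    }
  }
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE, na = "")
  sheet <- d$sample_sheet[, c("sample_id", "bio_rep", "set_memberships", "group", "is_control")]
  utils::write.csv(sheet, sheet_path, row.names = FALSE, quote = FALSE)
  invisible(d)
}

#' Aggregate technical and biological replicates
#'
#' Averages Cq values in two stages: technical replicates within each
#' biological replicate first, then biological replicates within each sample,
#' matching the usual qPCR replicate hierarchy. Wells whose technical
#' replicates disagree by more than `sd_flag_threshold` cycles are flagged in
#' the QC report but never removed or imputed.
#'
#' @param d a [cq_dataset()].
#' @param sd_flag_threshold technical-replicate SD (cycles) above which a
#'   (gene, unit) cell is flagged. Default 0.5 cycles.
#' @return A `cq_matrix`: list with `genes`, `samples`, `cq_mean` and
#'   `rep_sd` (both gene x sample; `rep_sd` is the SD across biological
#'   replicate means), and `qc` (data frame of flagged cells).
#' @export
aggregate_replicates <- function(d, sd_flag_threshold = 0.5) {
  stopifnot(inherits(d, "cq_dataset"))
  genes <- d$genes
  samples <- d$samples

  # stage 1: technical means per unit (missing-tolerant)
  unit_mean <- apply(d$cq, c(1, 2), function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  unit_sd <- apply(d$cq, c(1, 2), sample_sd)

  qc <- which(!is.na(unit_sd) & unit_sd > sd_flag_threshold, arr.ind = TRUE)
  qc_report <- data.frame(
    gene = genes[qc[, 1]],
    unit_id = d$units$unit_id[qc[, 2]],
    tech_sd = unit_sd[qc],
    stringsAsFactors = FALSE)

  # stage 2: biological means per sample
  cq_mean <- matrix(NA_real_, length(genes), length(samples),
                    dimnames = list(genes, samples))
  rep_sd <- cq_mean
  for (s in seq_along(samples)) {
    idx <- which(d$units$sample_id == samples[s])
    sub <- unit_mean[, idx, drop = FALSE]
    all_missing <- apply(sub, 1, function(x) all(is.na(x)))
    if (any(all_missing)) {
      warning(sprintf("no non-missing replicates for gene(s) %s in sample '%s'; cell left missing",
                      paste(genes[all_missing], collapse = ", "), samples[s]))
    }
    cq_mean[, s] <- ifelse(all_missing, NA_real_, rowMeans(sub, na.rm = TRUE))
    rep_sd[, s] <- apply(sub, 1, sample_sd)
  }

  structure(list(genes = genes, samples = samples,
                 cq_mean = cq_mean, rep_sd = rep_sd, qc = qc_report),
            class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("<cq_matrix> %d genes x %d samples; %d QC-flagged cell(s)\n",
              length(x$genes), length(x$samples), nrow(x$qc)))
  invisible(x)
}

#' Per-gene descriptive statistics of aggregated Cq values
#'
#' Computes mean, minimum, maximum, and the coefficient of variation of each
#' gene's Cq across samples. CV% is 100 * SD / mean with the sample SD
#' (n - 1 denominator), the convention used in expression-profiling surveys
#' of candidate reference genes.
#'
#' @param m a `cq_matrix` from [aggregate_replicates()].
#' @return Data frame with columns `gene`, `mean_cq`, `min_cq`, `max_cq`,
#'   `cv_percent`. Genes with fewer than two non-missing samples are dropped
#'   with a warning.
#' @export
descriptive_stats <- function(m) {
  stopifnot(inherits(m, "cq_matrix"))
  n_ok <- rowSums(!is.na(m$cq_mean))
  if (any(n_ok < 2L)) {
    warning(sprintf("gene(s) excluded (fewer than 2 samples): %s",
                    paste(m$genes[n_ok < 2L], collapse = ", ")))
  }
  keep <- which(n_ok >= 2L)
  out <- data.frame(
    gene = m$genes[keep],
    mean_cq = apply(m$cq_mean[keep, , drop = FALSE], 1, mean, na.rm = TRUE),
    min_cq = apply(m$cq_mean[keep, , drop = FALSE], 1, min, na.rm = TRUE),
    max_cq = apply(m$cq_mean[keep, , drop = FALSE], 1, max, na.rm = TRUE),
    stringsAsFactors = FALSE)
  sds <- apply(m$cq_mean[keep, , drop = FALSE], 1, sample_sd)
  out$cv_percent <- 100 * sds / out$mean_cq
  rownames(out) <- NULL
  out
}

# restrict a cq_matrix to a sample subset, dropping samples with any missing
# gene (listwise within the analyzed set)
subset_complete <- function(m, samples) {
  stopifnot(inherits(m, "cq_matrix"))
  keep <- intersect(samples, m$samples)
  sub <- m$cq_mean[, keep, drop = FALSE]
  complete <- colSums(is.na(sub)) == 0L
  if (!all(complete)) {
    message(sprintf("excluding %d sample(s) with missing Cq: %s",
                    sum(!complete), paste(keep[!complete], collapse = ", ")))
  }
  sub[, complete, drop = FALSE]
}
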