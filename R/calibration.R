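#' Amplification efficiency from a standard-curve slope
#'
#' For a calibration line of Cq against log10 template amount, the per-cycle
#' amplification efficiency is `E = 10^(-1/slope) - 1`; a perfect doubling
#' assay has slope -3.3219 and E = 1.
#'
#' @param slope slope of the calibration line (cycles per log10 template).
#' @return Efficiency as a fraction (E = 1 means perfect doubling).
#' @examples
#' efficiency_from_slope(-1 / log10(2))  # 1
#' @export
efficiency_from_slope <- function(slope) {
  assert_that(is.numeric(slope) && length(slope) == 1L && is.finite(slope),
              "`slope` must be a single finite number")
  if (slope == 0) stop("slope must be nonzero", call. = FALSE)
  10^(-1 / slope) - 1
}

#' Fit a qPCR standard curve to a dilution series
#'
#' Ordinary least-squares fit of mean Cq against log10 relative template
#' amount. The amplification efficiency follows from the slope via
#' [efficiency_from_slope()]. A non-negative slope (Cq not increasing with
#' dilution) yields `valid = FALSE` rather than an error, so screening runs
#' over many primer pairs can proceed.
#'
#' @param dilution_factors relative template amounts, positive and strictly
#'   decreasing (e.g. `1, 1/2, 1/4, 1/8, 1/16`); alternatively a
#'   `dilution_series` object from [simulate_dilution_series()].
#' @param cq mean Cq at each dilution point (cycles).
#' @param gene optional gene label carried into the result.
#' @return A `standard_curve`: list with `gene`, `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `valid`.
#' @examples
#' fit_standard_curve(c(1, 1/2, 1/4, 1/8, 1/16), c(20, 21, 22, 23, 24))
#' @export
fit_standard_curve <- function(dilution_factors, cq, gene = NA_character_) {
  if (inherits(dilution_factors, "dilution_series")) {
    s <- dilution_factors
    return(fit_standard_curve(s$dilution_factors, s$cq, s$gene))
  }
  assert_that(length(dilution_factors) == length(cq), "dilution/Cq length mismatch")
  assert_that(length(cq) >= 3L, "a standard curve needs at least 3 dilution points")
  assert_that(all(dilution_factors > 0), "dilution factors must be positive")
  assert_that(!any(duplicated(dilution_factors)), "dilution factors must be distinct")
  assert_that(all(diff(dilution_factors) < 0), "dilution factors must be strictly decreasing")

  x <- log10(dilution_factors)
  fit <- stats::lm(cq ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cq - mean(cq))^2)
  r_squared <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot

  valid <- is.finite(slope) && slope < 0
  eff <- if (valid) efficiency_from_slope(slope) else NA_real_
  structure(list(gene = gene, slope = slope, intercept = intercept,
                 r_squared = r_squared, efficiency = eff, valid = valid),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %s slope=%.4f R2=%.4f E=%.4f%s\n",
              if (is.na(x$gene)) "(unnamed)" else x$gene,
              x$slope, x$r_squared, x$efficiency,
              if (x$valid) "" else " [INVALID]"))
  invisible(x)
}

#' Convert mean Cq values to efficiency-corrected relative quantities
#'
#' Each gene's Cq values are converted to linear-scale relative quantities
#' `rq = (1 + E)^(minCq - Cq)`, where `minCq` is the gene's lowest Cq within
#' the analyzed sample set (the highest-expression sample is the calibrator,
#' so `rq <= 1` and `max rq = 1` per gene). Efficiency correction uses each
#' gene's own E, so a one-cycle difference means a (1+E)-fold expression
#' difference. Samples missing any gene's Cq are excluded listwise.
#'
#' @param m a `cq_matrix` from [aggregate_replicates()], or a plain numeric
#'   gene x sample matrix of mean Cq values with dimnames.
#' @param eff named vector of per-gene efficiencies as fractions in (0, 1.2];
#'   values above 1.1 (over-unity beyond usual assay tolerance) draw a
#'   warning.
#' @param samples optional sample subset defining the analyzed set; default
#'   all samples.
#' @return An `rq_matrix`: list with `genes`, `samples`, `rq` (gene x sample,
#'   positive), `efficiency`, and `calibrator_policy`.
#' @export
to_relative_quantities <- function(m, eff, samples = NULL) {
  cqm <- if (inherits(m, "cq_matrix")) {
    subset_complete(m, samples %||% m$samples)
  } else {
    stopifnot(is.matrix(m), !is.null(rownames(m)))
    sub <- m[, intersect(samples %||% colnames(m), colnames(m)), drop = FALSE]
    sub[, colSums(is.na(sub)) == 0L, drop = FALSE]
  }
  genes <- rownames(cqm)
  assert_that(all(genes %in% names(eff)),
              sprintf("missing efficiency for gene(s): %s",
                      paste(setdiff(genes, names(eff)), collapse = ", ")))
  e <- eff[genes]
  if (any(e <= 0)) stop("efficiency must be positive", call. = FALSE)
  if (any(e > 1.2)) stop("efficiency above 1.2 is not supported", call. = FALSE)
  if (any(e > 1.1)) {
    warning(sprintf("over-unity efficiency above 1.1 for: %s",
                    paste(genes[e > 1.1], collapse = ", ")))
  }
  all_missing <- apply(cqm, 1, function(x) all(is.na(x)))
  if (any(all_missing)) {
    stop(sprintf("gene(s) with no Cq in the analyzed set: %s",
                 paste(genes[all_missing], collapse = ", ")), call. = FALSE)
  }

  min_cq <- apply(cqm, 1, min)
  delta <- sweep(cqm, 1, min_cq, function(cq, m0) m0 - cq)  # minCq - Cq per gene
  rq <- (1 + e)^delta  # (1+e) recycles down columns, i.e. per gene row
  structure(list(genes = genes, samples = colnames(cqm), rq = rq,
                 efficiency = e,
                 calibrator_policy = "per-gene minimum Cq within analyzed set"),
            class = "rq_matrix")
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat(sprintf("<rq_matrix> %d genes x %d samples (calibrator: %s)\n",
              length(x$genes), length(x$samples), x$calibrator_policy))
  invisible(x)
}

#' Read a per-gene efficiency CSV
#'
#' @param path CSV with columns `gene`, `efficiency` (fraction, e.g. 0.90 to
#'   1.09).
#' @return Named numeric vector of efficiencies.
#' @export
read_efficiencies <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("gene", "efficiency") %in% names(tab)),
              "efficiency CSV needs columns gene, efficiency")
  stats::setNames(as.numeric(tab$efficiency), tab$gene)
}
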