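#' NormFinder model-based stability values
#'
#' Decomposes log2 relative quantities into sample loading, gene level,
#' intragroup noise and (in grouped mode) gene-by-group deviation, following
#' the variance-component model behind the NormFinder algorithm. Lower
#' stability values indicate more stably expressed genes.
#'
#' Grouped mode: within each group the log2 matrix is two-way centered
#' (per-sample mean across genes and per-gene group mean removed). The
#' intragroup variance of gene j in group g is estimated from the residual
#' variances `s2_gj` with the unbiasing implied by the centering,
#' `sigma2_gj = (J/(J-2)) * (s2_gj - sum_k s2_gk / (J*(J-1)))` for J genes,
#' clamped at zero. The intergroup deviation `d_gj` is the gene's group mean
#' after removing gene and group averages, so it sums to ~0 over genes within
#' a group and over groups within a gene. The stability value combines both:
#' `rho_j = mean_g( |d_gj| + sqrt(sigma2_gj / n_g) )`.
#'
#' Ungrouped mode treats all samples as one group and reports
#' `rho_j = sqrt(sigma2_j)`.
#'
#' @param rq an `rq_matrix` from [to_relative_quantities()] or a positive
#'   gene x sample matrix with dimnames.
#' @param groups optional per-sample group labels (e.g. treatment or tissue);
#'   omit or `NULL` for ungrouped mode. Grouped mode needs >= 2 groups with
#'   >= 2 samples each.
#' @param small_sample_correction apply the `J/(J-2)` variance unbiasing
#'   (default `TRUE`); with it off, raw residual variances are used.
#' @return A `normfinder_result`: list with `stability` (named, lower =
#'   more stable), `ranks`, `intragroup_var` (gene x group), `intergroup_dev`
#'   (gene x group, grouped mode only), `grouped`.
#' @export
normfinder_stability <- function(rq, groups = NULL, small_sample_correction = TRUE) {
  x <- if (inherits(rq, "rq_matrix")) rq$rq else rq
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  assert_that(all(is.finite(x)) && all(x > 0), "relative quantities must be positive")
  gn <- nrow(x)
  assert_that(gn >= 3L, "NormFinder requires at least 3 genes")
  y <- log2(x)
  grouped <- !is.null(groups) && length(unique(groups)) > 1L

  if (!grouped) {
    s2 <- nf_intragroup_var(y, small_sample_correction)
    rho <- sqrt(s2)
    res <- list(stability = rho,
                ranks = rank_scores(rho),
                intragroup_var = matrix(s2, ncol = 1, dimnames = list(names(s2), "all")),
                intergroup_dev = NULL,
                grouped = FALSE)
    return(structure(res, class = "normfinder_result"))
  }

  assert_that(length(groups) == ncol(x), "one group label per sample required")
  groups <- as.character(groups)
  glev <- unique(groups)
  n_g <- table(factor(groups, levels = glev))
  if (any(n_g < 2L)) {
    stop(sprintf("grouped mode needs >= 2 samples per group; singleton group(s): %s",
                 paste(names(n_g)[n_g < 2L], collapse = ", ")), call. = FALSE)
  }

  s2 <- matrix(NA_real_, gn, length(glev), dimnames = list(rownames(x), glev))
  gene_group_mean <- s2
  for (g in glev) {
    yg <- y[, groups == g, drop = FALSE]
    s2[, g] <- nf_intragroup_var(yg, small_sample_correction)
    # remove the per-sample loading before taking the gene's group mean
    yg_centered <- sweep(yg, 2, colMeans(yg))
    gene_group_mean[, g] <- rowMeans(yg_centered)
  }
  # intergroup deviation: two-way center the gene x group mean table
  d <- gene_group_mean -
    outer(rowMeans(gene_group_mean), rep(1, length(glev))) -
    outer(rep(1, gn), colMeans(gene_group_mean)) +
    mean(gene_group_mean)

  per_group <- abs(d) + sqrt(sweep(s2, 2, as.numeric(n_g), "/"))
  rho <- rowMeans(per_group)
  structure(list(stability = rho,
                 ranks = rank_scores(rho),
                 intragroup_var = s2,
                 intergroup_dev = d,
                 grouped = TRUE),
            class = "normfinder_result")
}

# moment estimator of per-gene intragroup variance from two-way-centered
# residuals of a log2 gene x sample matrix
nf_intragroup_var <- function(y, correct = TRUE) {
  j <- nrow(y)
  n <- ncol(y)
  assert_that(n >= 2L, "variance estimation needs >= 2 samples")
  r <- y - outer(rowMeans(y), rep(1, n)) - outer(rep(1, j), colMeans(y)) + mean(y)
  s2 <- apply(r, 1, function(z) sum(z^2) / (n - 1))
  if (correct) {
    assert_that(j >= 3L, "small-sample correction needs >= 3 genes")
    s2 <- (j / (j - 2)) * (s2 - sum(s2) / (j * (j - 1)))
  }
  pmax(stats::setNames(s2, rownames(y)), 0)
}

#' @export
print.normfinder_result <- function(x, ...) {
  best <- names(sort(x$stability))[1:min(3, length(x$stability))]
  cat(sprintf("<normfinder_result> %d genes (%s); most stable: %s\n",
              length(x$stability), if (x$grouped) "grouped" else "ungrouped",
              paste(best, collapse = ", ")))
  invisible(x)
}
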