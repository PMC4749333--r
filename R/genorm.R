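#' SD of pairwise log2 expression ratios between two genes
#'
#' The geNorm building block: for genes j and k with relative quantities
#' `rq_j`, `rq_k` across the same samples, `V_jk` is the sample SD (n - 1
#' denominator) of `A_jk = log2(rq_j / rq_k)`. Two perfectly co-regulated
#' (or both perfectly stable) genes give `V_jk = 0`.
#'
#' @param rq_j,rq_k positive relative quantities of the two genes, equal
#'   length >= 2.
#' @return The pairwise variation `V_jk` (dimensionless, log2 units).
#' @examples
#' pairwise_log_ratio_sd(c(1, 2, 4), c(2, 4, 8))  # 0
#' @export
pairwise_log_ratio_sd <- function(rq_j, rq_k) {
  assert_that(length(rq_j) == length(rq_k), "vectors must have equal length")
  assert_that(length(rq_j) >= 2L, "need at least 2 samples")
  assert_that(all(rq_j > 0) && all(rq_k > 0), "relative quantities must be positive")
  stats::sd(log2(rq_j / rq_k))
}

# extract the positive gene x sample matrix from an rq_matrix or plain matrix
as_rq <- function(rq) {
  x <- if (inherits(rq, "rq_matrix")) rq$rq else rq
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  assert_that(all(is.finite(x)) && all(x > 0), "relative quantities must be positive and finite")
  x
}

#' geNorm expression-stability measure M
#'
#' For each gene j, `M_j` is the mean over all other genes k of the pairwise
#' variation `V_jk` ([pairwise_log_ratio_sd()]). Genes with the lowest M have
#' the most stable expression relative to the rest of the candidate panel.
#'
#' @param rq an `rq_matrix` from [to_relative_quantities()] or a positive
#'   gene x sample matrix with rownames.
#' @return Named numeric vector of M values (one per gene).
#' @export
genorm_m <- function(rq) {
  x <- as_rq(rq)
  g <- nrow(x)
  assert_that(g >= 3L, "geNorm M requires at least 3 genes")
  assert_that(ncol(x) >= 2L, "geNorm M requires at least 2 samples")
  a <- log2(x)
  m <- numeric(g)
  for (j in seq_len(g)) {
    v <- vapply(seq_len(g)[-j], function(k) stats::sd(a[j, ] - a[k, ]), numeric(1))
    m[j] <- mean(v)
  }
  stats::setNames(m, rownames(x))
}

#' geNorm stepwise gene exclusion
#'
#' Repeatedly removes the gene with the highest M and recomputes M among the
#' remaining genes until two genes are left. These final two cannot be
#' separated (their M values are equal by construction) and are reported as a
#' tied best pair. Ties in the highest M are broken by removing the
#' lexicographically later gene identifier, making the procedure
#' deterministic.
#'
#' @param rq an `rq_matrix` or positive gene x sample matrix.
#' @param tie_final how the final tied pair enters the gene ranking:
#'   `"midrank"` (both rank 1.5, the default) or `"lexicographic"` (ranks 1
#'   and 2 by gene id).
#' @return A `genorm_result`: list with `m_values` (first-pass M),
#'   `exclusion_order` (data frame: least to most stable, with the M at each
#'   elimination step), `final_pair`, and `ranks` (named, most stable = 1).
#' @export
genorm_rank <- function(rq, tie_final = c("midrank", "lexicographic")) {
  tie_final <- match.arg(tie_final)
  x <- as_rq(rq)
  assert_that(nrow(x) >= 3L, "geNorm ranking requires at least 3 genes")
  m_first <- genorm_m(x)

  remaining <- rownames(x)
  excluded <- character(0)
  m_at_step <- numeric(0)
  while (length(remaining) > 2L) {
    m <- genorm_m(x[remaining, , drop = FALSE])
    # highest M leaves; tie -> lexicographically later id
    worst <- names(m)[m == max(m)]
    worst <- worst[order(worst, decreasing = TRUE)][1]
    excluded <- c(excluded, worst)
    m_at_step <- c(m_at_step, m[worst])
    remaining <- setdiff(remaining, worst)
  }
  final_pair <- sort(remaining)
  m_final <- genorm_m_pairless(x, final_pair)

  exclusion_order <- data.frame(
    gene = c(excluded, final_pair),
    m_at_exclusion = c(m_at_step, rep(m_final, 2)),
    step = c(seq_along(excluded), NA, NA),
    stringsAsFactors = FALSE)

  g <- nrow(x)
  ranks <- stats::setNames(rep(NA_real_, g), rownames(x))
  ranks[rev(excluded)] <- seq(3, g)
  ranks[final_pair] <- if (tie_final == "midrank") c(1.5, 1.5) else c(1, 2)

  structure(list(m_values = m_first, exclusion_order = exclusion_order,
                 final_pair = final_pair, ranks = ranks),
            class = "genorm_result")
}

# M of the two last genes: mean pairwise variation within the pair
genorm_m_pairless <- function(x, pair) {
  pairwise_log_ratio_sd(x[pair[1], ], x[pair[2], ])
}

#' @export
print.genorm_result <- function(x, ...) {
  cat(sprintf("<genorm_result> %d genes; most stable pair: %s (M = %.4f)\n",
              length(x$m_values), paste(x$final_pair, collapse = "/"),
              x$exclusion_order$m_at_exclusion[nrow(x$exclusion_order)]))
  invisible(x)
}

#' Per-sample normalization factor over a reference-gene subset
#'
#' The normalization factor of sample i is the geometric mean of the relative
#' quantities of the chosen reference genes in that sample.
#'
#' @param rq an `rq_matrix` or positive gene x sample matrix.
#' @param subset character vector of gene identifiers.
#' @return Named numeric vector of per-sample normalization factors.
#' @export
normalization_factor <- function(rq, subset) {
  x <- as_rq(rq)
  assert_that(length(subset) >= 1L, "reference subset must be nonempty")
  assert_that(all(subset %in% rownames(x)),
              sprintf("gene(s) not in matrix: %s",
                      paste(setdiff(subset, rownames(x)), collapse = ", ")))
  apply(x[subset, , drop = FALSE], 2, geomean)
}

#' Pairwise-variation curve and optimal number of reference genes
#'
#' Computes `V(n, n+1)`, the sample SD of `log2(NF_n / NF_{n+1})` where
#' `NF_n` is the normalization factor over the n most stable genes, for
#' n = 2 ... G-1. The smallest n with `V(n, n+1)` below the cutoff (0.15 by
#' convention) is the optimal number of reference genes: adding the
#' (n+1)-th gene no longer changes normalization appreciably.
#'
#' @param rq an `rq_matrix` or positive gene x sample matrix.
#' @param ranking a `genorm_result` from [genorm_rank()], or a character
#'   vector of genes from most to least stable.
#' @param cutoff V threshold below which no further gene is required
#'   (default 0.15).
#' @return List with `v_curve` (data frame: `n`, `v`), `optimal_n` (integer,
#'   or `NA` with `reached = FALSE` when no V falls below the cutoff), and
#'   `cutoff`.
#' @export
pairwise_variation_curve <- function(rq, ranking, cutoff = 0.15) {
  x <- as_rq(rq)
  order_best_first <- if (inherits(ranking, "genorm_result")) {
    rev(ranking$exclusion_order$gene)
  } else {
    as.character(ranking)
  }
  assert_that(setequal(order_best_first, rownames(x)),
              "ranking must cover exactly the genes of the matrix")
  g <- nrow(x)
  assert_that(g >= 3L, "V-curve requires at least 3 genes")

  a <- log2(x)[order_best_first, , drop = FALSE]
  ns <- 2:(g - 1)
  v <- vapply(ns, function(n) {
    log_nf_n <- colMeans(a[seq_len(n), , drop = FALSE])
    log_nf_n1 <- colMeans(a[seq_len(n + 1), , drop = FALSE])
    stats::sd(log_nf_n - log_nf_n1)
  }, numeric(1))

  below <- which(v < cutoff)
  optimal_n <- if (length(below) > 0L) ns[below[1]] else NA_integer_
  list(v_curve = data.frame(n = ns, v = v),
       optimal_n = optimal_n,
       reached = length(below) > 0L,
       cutoff = cutoff)
}
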