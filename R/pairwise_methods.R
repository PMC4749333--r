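#' BestKeeper descriptive stability statistics
#'
#' Operates on raw mean Cq values (no efficiency correction), as the original
#' BestKeeper tool does. For each gene it reports the SD and CV% of its Cq
#' across samples; the BestKeeper index of a sample is the geometric mean of
#' all candidate Cq values in that sample, and each gene's Pearson
#' correlation with the index is reported. Ranking is by ascending Cq SD by
#' default (correlation-based ranking is available), since a low-SD gene is
#' the one whose Cq moves least across conditions.
#'
#' @param m a `cq_matrix` from [aggregate_replicates()] or a numeric
#'   gene x sample Cq matrix with dimnames; samples with any missing gene are
#'   excluded listwise.
#' @param rank_by `"sd"` (default) or `"r"` (descending |r|).
#' @return A `bestkeeper_result`: data frame `table` (gene, sd_cq, cv_cq,
#'   pearson_r, rank), vector `index` (per-sample geometric mean Cq), and
#'   `ranks`.
#' @export
bestkeeper <- function(m, rank_by = c("sd", "r")) {
  rank_by <- match.arg(rank_by)
  cqm <- if (inherits(m, "cq_matrix")) subset_complete(m, m$samples) else {
    stopifnot(is.matrix(m), !is.null(rownames(m)))
    m[, colSums(is.na(m)) == 0L, drop = FALSE]
  }
  assert_that(nrow(cqm) >= 2L, "BestKeeper requires at least 2 genes")
  assert_that(ncol(cqm) >= 3L, "BestKeeper requires at least 3 samples")
  assert_that(all(cqm > 0), "Cq values must be positive")

  sd_cq <- apply(cqm, 1, stats::sd)
  cv_cq <- 100 * sd_cq / rowMeans(cqm)
  index <- apply(cqm, 2, geomean)
  r <- if (stats::sd(index) == 0) rep(NA_real_, nrow(cqm)) else {
    apply(cqm, 1, function(x) if (stats::sd(x) == 0) NA_real_ else stats::cor(x, index))
  }
  ranks <- if (rank_by == "sd") rank_scores(sd_cq) else rank_scores(-abs(r))
  tab <- data.frame(gene = rownames(cqm), sd_cq = sd_cq, cv_cq = cv_cq,
                    pearson_r = r, rank = ranks,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, index = index, ranks = stats::setNames(ranks, rownames(cqm))),
            class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  best <- x$table$gene[order(x$table$rank)][1:min(3, nrow(x$table))]
  cat(sprintf("<bestkeeper_result> %d genes; lowest Cq SD: %s\n",
              nrow(x$table), paste(best, collapse = ", ")))
  invisible(x)
}

#' Comparative delta-Ct stability scores
#'
#' For every ordered gene pair (j, k) the per-sample difference
#' `dCq_i = Cq[j, i] - Cq[k, i]` is formed; gene j's score is the mean over
#' all partners k of the sample SD of these differences. A gene whose Cq
#' moves in lockstep with the other candidates (stable relative expression)
#' scores low. Works on raw mean Cq, no efficiency correction.
#'
#' @param m a `cq_matrix` or numeric gene x sample Cq matrix with dimnames;
#'   incomplete samples are excluded listwise.
#' @return A `delta_ct_result`: data frame `table` (gene, mean_pairwise_sd,
#'   rank) and vector `ranks`.
#' @export
delta_ct_stability <- function(m) {
  cqm <- if (inherits(m, "cq_matrix")) subset_complete(m, m$samples) else {
    stopifnot(is.matrix(m), !is.null(rownames(m)))
    m[, colSums(is.na(m)) == 0L, drop = FALSE]
  }
  g <- nrow(cqm)
  assert_that(g >= 3L, "delta-Ct method requires at least 3 genes")
  assert_that(ncol(cqm) >= 2L, "delta-Ct method requires at least 2 samples")

  score <- vapply(seq_len(g), function(j) {
    mean(vapply(seq_len(g)[-j], function(k) stats::sd(cqm[j, ] - cqm[k, ]), numeric(1)))
  }, numeric(1))
  names(score) <- rownames(cqm)
  ranks <- rank_scores(score)
  tab <- data.frame(gene = rownames(cqm), mean_pairwise_sd = score, rank = ranks,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, ranks = ranks), class = "delta_ct_result")
}

#' @export
print.delta_ct_result <- function(x, ...) {
  best <- x$table$gene[order(x$table$rank)][1:min(3, nrow(x$table))]
  cat(sprintf("<delta_ct_result> %d genes; most stable: %s\n",
              nrow(x$table), paste(best, collapse = ", ")))
  invisible(x)
}
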