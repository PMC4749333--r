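#' Rank stability scores with midrank ties
#'
#' Rank 1 is the most stable gene: the lowest score when `ascending = TRUE`
#' (the convention of all four stability methods), the highest otherwise.
#' Tied scores receive the mean of the ranks they span.
#'
#' @param scores named numeric vector, all finite.
#' @param ascending rank lowest score first (default `TRUE`).
#' @return Named numeric vector of (possibly half-integer) ranks.
#' @examples
#' rank_scores(c(a = 0.2, b = 0.5, c = 0.3))
#' @export
rank_scores <- function(scores, ascending = TRUE) {
  if (any(!is.finite(scores))) {
    stop(sprintf("non-finite score(s) for: %s",
                 paste(names(scores)[!is.finite(scores)], collapse = ", ")), call. = FALSE)
  }
  r <- rank(if (ascending) scores else -scores, ties.method = "average")
  stats::setNames(as.numeric(r), names(scores))
}

#' Comprehensive reference-gene ranking by geometric mean of method ranks
#'
#' Aggregates the per-method gene rankings (geNorm, NormFinder, BestKeeper,
#' comparative delta-Ct) into a single comprehensive ranking, RefFinder
#' style: each gene's aggregate score is the geometric mean of its ranks
#' across methods, and genes are ordered by ascending geometric mean
#' (lexicographic gene id on exact ties). Half-integer ranks, such as the
#' geNorm final pair at 1.5/1.5, are legitimate inputs.
#'
#' @param method_ranks gene x method matrix or data frame of ranks (each
#'   column a permutation of 1..G up to midrank ties), with gene rownames;
#'   alternatively a named list of rank vectors sharing the same gene set.
#' @return A `stability_table` data frame: one row per gene, per-method rank
#'   columns, `geomean_rank`, and integer `comprehensive_rank`, ordered most
#'   stable first.
#' @export
comprehensive_rank <- function(method_ranks) {
  if (is.list(method_ranks) && !is.data.frame(method_ranks)) {
    genes <- names(method_ranks[[1]])
    assert_that(!is.null(genes), "rank vectors must be named by gene")
    for (m in method_ranks) {
      assert_that(setequal(names(m), genes), "all methods must rank the same gene set")
    }
    method_ranks <- vapply(method_ranks, function(m) m[genes], numeric(length(genes)))
    rownames(method_ranks) <- genes
  }
  rk <- as.matrix(method_ranks)
  assert_that(ncol(rk) >= 2L, "need at least 2 methods to aggregate")
  assert_that(!is.null(rownames(rk)), "rank table must have gene rownames")
  if (any(is.na(rk))) {
    bad <- rownames(rk)[apply(is.na(rk), 1, any)]
    stop(sprintf("missing rank for gene(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }

  geo <- apply(rk, 1, geomean)
  ord <- order(geo, rownames(rk))
  out <- data.frame(gene = rownames(rk), rk, geomean_rank = geo,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)[ord, ]
  out$comprehensive_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("stability_table", "data.frame")
  out
}

#' @export
print.stability_table <- function(x, ...) {
  cat(sprintf("<stability_table> %d genes; comprehensive top 4: %s\n",
              nrow(x), paste(utils::head(x$gene, 4), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... %d more genes\n", nrow(x) - 10))
  invisible(x)
}
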