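#' Run the full reference-gene stability analysis
#'
#' Orchestrates the complete evaluation for each declared sample set: listwise
#' completion, per-set efficiency-corrected relative quantities (the
#' calibrator is recomputed within each set so sets are self-contained),
#' geNorm stepwise ranking with the pairwise-variation curve and optimal
#' reference-gene number, NormFinder (grouped when every group in the set has
#' at least two samples, ungrouped otherwise), BestKeeper and comparative
#' delta-Ct on raw mean Cq, and the comprehensive geometric-mean ranking.
#' The run is fully deterministic: no stage draws random numbers.
#'
#' @param dataset a [cq_dataset()].
#' @param eff named per-gene efficiency fractions.
#' @param sets character vector of sample sets to analyze; default every set
#'   declared in the sample sheet.
#' @param v_cutoff pairwise-variation cutoff for the optimal gene number
#'   (default 0.15).
#' @param sd_flag_threshold technical-replicate QC threshold in cycles
#'   (default 0.5).
#' @param genorm_tie how the geNorm final pair enters the consensus
#'   (`"midrank"` or `"lexicographic"`).
#' @param out_dir optional directory; when given, per-set consensus and
#'   V-curve CSVs, the QC report, and descriptive statistics are written
#'   there.
#' @return A `refstab_analysis`: list with `cq_matrix`, `gene_stats`, per-set
#'   results (each holding `rq`, `genorm`, `v_curve`, `normfinder`,
#'   `bestkeeper`, `delta_ct`, `consensus`), and a `log` of stage decisions.
#' @export
run_full_analysis <- function(dataset, eff, sets = NULL,
                              v_cutoff = 0.15, sd_flag_threshold = 0.5,
                              genorm_tie = c("midrank", "lexicographic"),
                              out_dir = NULL) {
  stopifnot(inherits(dataset, "cq_dataset"))
  genorm_tie <- match.arg(genorm_tie)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  m <- aggregate_replicates(dataset, sd_flag_threshold)
  note("aggregated %d genes x %d samples; %d QC-flagged cell(s)",
       length(m$genes), length(m$samples), nrow(m$qc))
  gene_stats <- descriptive_stats(m)

  declared <- sample_sets(dataset)
  sets <- sets %||% names(declared)
  assert_that(all(sets %in% names(declared)),
              sprintf("unknown sample set(s): %s",
                      paste(setdiff(sets, names(declared)), collapse = ", ")))

  sheet <- unique(dataset$sample_sheet[, c("sample_id", "group")])
  per_set <- list()
  for (s in sets) {
    samples <- declared[[s]]
    cq_sub <- subset_complete(m, samples)
    note("set '%s': %d of %d samples complete", s, ncol(cq_sub), length(samples))
    assert_that(ncol(cq_sub) >= 3L, sprintf("set '%s' has fewer than 3 complete samples", s))

    rq <- to_relative_quantities(m, eff, samples = colnames(cq_sub))
    gn <- genorm_rank(rq, tie_final = genorm_tie)
    vc <- pairwise_variation_curve(rq, gn, cutoff = v_cutoff)
    note("set '%s': geNorm best pair %s; optimal n = %s", s,
         paste(gn$final_pair, collapse = "/"),
         if (vc$reached) vc$optimal_n else "not reached")

    groups <- sheet$group[match(colnames(cq_sub), sheet$sample_id)]
    tab <- table(groups)
    grouped <- length(tab) >= 2L && all(tab >= 2L)
    nf <- normfinder_stability(rq, groups = if (grouped) groups else NULL)
    note("set '%s': NormFinder %s", s,
         if (grouped) sprintf("grouped (%d groups)", length(tab)) else "ungrouped")

    bk <- bestkeeper(cq_sub)
    dc <- delta_ct_stability(cq_sub)
    consensus <- comprehensive_rank(list(genorm = gn$ranks,
                                         normfinder = nf$ranks,
                                         bestkeeper = bk$ranks,
                                         deltact = dc$ranks))
    per_set[[s]] <- list(samples = colnames(cq_sub), rq = rq, genorm = gn,
                         v_curve = vc, normfinder = nf, bestkeeper = bk,
                         delta_ct = dc, consensus = consensus)
  }

  res <- structure(list(cq_matrix = m, gene_stats = gene_stats,
                        sets = per_set, log = log),
                   class = "refstab_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' @export
print.refstab_analysis <- function(x, ...) {
  cat(sprintf("<refstab_analysis> %d genes, %d sample sets\n",
              length(x$cq_matrix$genes), length(x$sets)))
  for (s in names(x$sets)) {
    top <- utils::head(x$sets[[s]]$consensus$gene, 4)
    vc <- x$sets[[s]]$v_curve
    cat(sprintf("  %-9s top-4: %s | optimal n = %s\n", s,
                paste(top, collapse = ", "),
                if (vc$reached) vc$optimal_n else "not reached"))
  }
  invisible(x)
}

#' Write analysis report tables to CSV
#'
#' Emits, per sample set, a consensus table (per-method ranks, geometric
#' mean, comprehensive rank) and the pairwise-variation curve, plus the
#' per-gene descriptive statistics and the replicate QC report. Output is
#' deterministic: a rerun with the same inputs is byte-identical.
#'
#' @param res a `refstab_analysis` from [run_full_analysis()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(res, out_dir) {
  stopifnot(inherits(res, "refstab_analysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wr(res$gene_stats, "gene_stats.csv")
  wr(res$cq_matrix$qc, "qc_flags.csv")
  for (s in names(res$sets)) {
    set <- res$sets[[s]]
    wr(as.data.frame(set$consensus), sprintf("consensus_%s.csv", s))
    vc <- set$v_curve$v_curve
    vc$cutoff <- set$v_curve$cutoff
    vc$optimal_n <- set$v_curve$optimal_n
    wr(vc, sprintf("vcurve_%s.csv", s))
    gn <- set$genorm$exclusion_order
    gn$rank <- set$genorm$ranks[gn$gene]
    wr(gn, sprintf("genorm_%s.csv", s))
  }
  invisible(paths)
}
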