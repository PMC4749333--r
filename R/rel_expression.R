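#' Efficiency-corrected relative expression ratio
#'
#' REST-style fold change of a target gene between a control and a treatment
#' condition, normalized by one or more reference genes:
#' `R = (1+E_t)^(meanCq_t,ctrl - meanCq_t,trt) / geomean_r (1+E_r)^(meanCq_r,ctrl - meanCq_r,trt)`.
#' With several reference genes the per-reference normalization factors are
#' combined by geometric mean. A reference whose own expression shifts with
#' treatment biases R by exactly its fold change, which is why unstable
#' reference genes obscure normalization.
#'
#' @param cq long-format data frame with columns `gene`, `condition`,
#'   `replicate`, `cq`: one row per well, replicate Cq values already
#'   averaged over technical replicates (or raw; all rows of a
#'   gene x condition are averaged).
#' @param target target gene identifier.
#' @param refs character vector of reference gene identifiers (>= 1).
#' @param eff named per-gene efficiency fractions covering target and refs.
#' @param control,treatment the two condition labels (defaults `"control"`,
#'   `"treatment"`).
#' @return An `expression_ratio_result`: list with `target`, `refs`, `ratio`,
#'   `log2_ratio`, `per_replicate_ratios` (one per treatment replicate,
#'   against the control means), and condition means.
#' @export
expression_ratio <- function(cq, target, refs, eff,
                             control = "control", treatment = "treatment") {
  check_long_cq(cq)
  assert_that(length(refs) >= 1L, "at least one reference gene is required")
  genes <- c(target, refs)
  missing_eff <- setdiff(genes, names(eff))
  assert_that(length(missing_eff) == 0L,
              sprintf("missing efficiency for: %s", paste(missing_eff, collapse = ", ")))

  mean_cq <- function(g, cond) {
    v <- cq$cq[cq$gene == g & cq$condition == cond]
    assert_that(length(v) >= 2L,
                sprintf("need >= 2 replicates for gene '%s' in condition '%s'", g, cond))
    mean(v)
  }
  log2_fc <- function(g) (mean_cq(g, control) - mean_cq(g, treatment)) * log2(1 + eff[[g]])

  num <- log2_fc(target)
  den <- mean(vapply(refs, log2_fc, numeric(1)))  # geometric mean on the log scale
  log2_ratio <- num - den

  # per treatment-replicate ratios against the control means
  trt_reps <- unique(cq$replicate[cq$condition == treatment])
  per_rep <- vapply(trt_reps, function(r) {
    one <- function(g) {
      v <- cq$cq[cq$gene == g & cq$condition == treatment & cq$replicate == r]
      (mean_cq(g, control) - mean(v)) * log2(1 + eff[[g]])
    }
    2^(one(target) - mean(vapply(refs, one, numeric(1))))
  }, numeric(1))

  structure(list(target = target, refs = refs,
                 ratio = 2^log2_ratio, log2_ratio = unname(log2_ratio),
                 per_replicate_ratios = stats::setNames(per_rep, trt_reps),
                 control = control, treatment = treatment),
            class = "expression_ratio_result")
}

#' @export
print.expression_ratio_result <- function(x, ...) {
  cat(sprintf("<expression_ratio> %s vs %s/%s, refs %s: ratio = %.4g\n",
              x$target, x$treatment, x$control,
              paste(x$refs, collapse = "+"), x$ratio))
  if (!is.null(x$p_value)) {
    cat(sprintf("  randomization p = %.4g (%d permutations)\n", x$p_value, x$n_permutations))
  }
  invisible(x)
}

#' Fixed-reallocation randomization test for an expression ratio
#'
#' Tests whether the observed fold change of the target gene could arise by
#' chance, by repeatedly reallocating the condition labels of whole
#' replicate samples (jointly across target and reference genes, preserving
#' the within-sample pairing) and recomputing the ratio. The two-sided
#' p-value is the proportion of reallocations with `|log R|` at least as
#' large as observed, with +1 smoothing in numerator and denominator. When
#' fewer than 10 distinct reallocations exist, all of them are enumerated
#' instead (with a warning) and the exact proportion is returned.
#'
#' @inheritParams expression_ratio
#' @param n_permutations number of random reallocations (>= 1000
#'   recommended; default 2000).
#' @param seed integer seed; required for reproducibility.
#' @return The `expression_ratio_result` of the observed data, augmented
#'   with `p_value`, `n_permutations`, `exact` (enumeration flag), and
#'   `seed`.
#' @export
randomization_test <- function(cq, target, refs, eff,
                               control = "control", treatment = "treatment",
                               n_permutations = 2000, seed) {
  assert_that(!missing(seed) && is.finite(seed), "an integer `seed` is required")
  assert_that(n_permutations >= 1L, "n_permutations must be positive")
  obs <- expression_ratio(cq, target, refs, eff, control, treatment)
  genes <- c(target, refs)

  # per-sample summary statistic: z_i = efficiency-weighted normalized log2
  # target level of replicate sample i; log R is a difference of z means
  reps <- unique(cq[, c("condition", "replicate")])
  z <- vapply(seq_len(nrow(reps)), function(i) {
    one <- function(g) {
      v <- cq$cq[cq$gene == g & cq$condition == reps$condition[i] &
                   cq$replicate == reps$replicate[i]]
      assert_that(length(v) >= 1L,
                  sprintf("gene '%s' missing in %s replicate %s",
                          g, reps$condition[i], reps$replicate[i]))
      -mean(v) * log2(1 + eff[[g]])
    }
    one(target) - mean(vapply(refs, one, numeric(1)))
  }, numeric(1))
  is_trt <- reps$condition == treatment
  n <- length(z)
  n_trt <- sum(is_trt)
  assert_that(n_trt >= 1L && n_trt < n, "both conditions must be non-empty")

  stat <- function(trt_idx) {
    abs(mean(z[trt_idx]) - mean(z[-trt_idx]))
  }
  obs_stat <- stat(which(is_trt))

  n_distinct <- choose(n, n_trt)
  if (n_distinct < 10) {
    warning(sprintf("only %d distinct reallocations; using exact enumeration", n_distinct))
    splits <- utils::combn(n, n_trt)
    perm <- apply(splits, 2, stat)
    p <- mean(perm >= obs_stat - 1e-12)
    exact <- TRUE
    n_used <- n_distinct
  } else {
    set.seed(as.integer(seed))
    perm <- vapply(seq_len(n_permutations),
                   function(i) stat(sample.int(n, n_trt)), numeric(1))
    p <- (1 + sum(perm >= obs_stat - 1e-12)) / (1 + n_permutations)
    exact <- FALSE
    n_used <- n_permutations
  }

  obs$p_value <- p
  obs$n_permutations <- n_used
  obs$exact <- exact
  obs$seed <- seed
  obs
}

check_long_cq <- function(cq) {
  req <- c("gene", "condition", "replicate", "cq")
  assert_that(is.data.frame(cq) && all(req %in% names(cq)),
              paste("long Cq table needs columns:", paste(req, collapse = ", ")))
  assert_that(all(is.finite(cq$cq)), "Cq values must be finite")
}

#' Read a long-format validation Cq CSV
#'
#' @param path CSV with columns `gene`, `condition`, `replicate`, `cq`.
#' @return Data frame suitable for [expression_ratio()].
#' @export
read_long_cq <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_long_cq(tab)
  tab
}
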