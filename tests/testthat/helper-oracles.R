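# Independent brute-force oracles. These re-derive every statistic from its
# definition with explicit loops, sharing no code with the package internals.

oracle_genorm_m <- function(rq) {
  g <- nrow(rq)
  m <- numeric(g)
  for (j in 1:g) {
    vs <- c()
    for (k in 1:g) {
      if (k == j) next
      a <- log2(rq[j, ] / rq[k, ])
      vs <- c(vs, sqrt(sum((a - mean(a))^2) / (length(a) - 1)))
    }
    m[j] <- mean(vs)
  }
  names(m) <- rownames(rq)
  m
}

# exhaustive stepwise exclusion, recomputing M from scratch at each step
oracle_genorm_exclusion <- function(rq) {
  remaining <- rownames(rq)
  out <- character(0)
  while (length(remaining) > 2) {
    m <- oracle_genorm_m(rq[remaining, , drop = FALSE])
    worst_val <- max(m)
    cand <- sort(names(m)[abs(m - worst_val) < 1e-15], decreasing = TRUE)[1]
    out <- c(out, cand)
    remaining <- setdiff(remaining, cand)
  }
  c(out, sort(remaining))
}

oracle_v_curve <- function(rq, order_best_first) {
  g <- nrow(rq)
  sapply(2:(g - 1), function(n) {
    nf_n <- apply(rq[order_best_first[1:n], , drop = FALSE], 2,
                  function(x) prod(x)^(1 / length(x)))
    nf_n1 <- apply(rq[order_best_first[1:(n + 1)], , drop = FALSE], 2,
                   function(x) prod(x)^(1 / length(x)))
    a <- log2(nf_n / nf_n1)
    sqrt(sum((a - mean(a))^2) / (length(a) - 1))
  })
}

oracle_delta_ct <- function(cq) {
  g <- nrow(cq)
  score <- numeric(g)
  for (j in 1:g) {
    sds <- c()
    for (k in 1:g) {
      if (k == j) next
      d <- cq[j, ] - cq[k, ]
      sds <- c(sds, sqrt(sum((d - mean(d))^2) / (length(d) - 1)))
    }
    score[j] <- mean(sds)
  }
  names(score) <- rownames(cq)
  score
}

oracle_bestkeeper <- function(cq) {
  g <- nrow(cq)
  n <- ncol(cq)
  sd_cq <- apply(cq, 1, function(x) sqrt(sum((x - mean(x))^2) / (n - 1)))
  index <- apply(cq, 2, function(x) prod(x)^(1 / length(x)))
  r <- apply(cq, 1, function(x) {
    sum((x - mean(x)) * (index - mean(index))) /
      sqrt(sum((x - mean(x))^2) * sum((index - mean(index))^2))
  })
  list(sd_cq = sd_cq, cv_cq = 100 * sd_cq / rowMeans(cq), index = index, r = r)
}

# random positive gene x sample RQ matrix
random_rq <- function(g, n, seed) {
  set.seed(seed)
  m <- matrix(2^rnorm(g * n, 0, 1), g, n,
              dimnames = list(paste0("g", seq_len(g)), paste0("s", seq_len(n))))
  m
}

# Spearman correlation between injected noise and recovered ranking for one
# simulated replicate of the default 25-gene / 20-sample design ('all' set)
recovery_spearman <- function(seed, tau = seq(0.02, 0.8, length.out = 25)) {
  sim <- simulate_cq_dataset(simulation_config(tau = tau, seed = seed))
  m <- aggregate_replicates(sim$dataset)
  rq <- to_relative_quantities(m, sim$efficiency)
  gn <- genorm_rank(rq)
  nf <- normfinder_stability(rq)
  bk <- bestkeeper(m)
  dc <- delta_ct_stability(m)
  cons <- comprehensive_rank(list(genorm = gn$ranks, normfinder = nf$ranks,
                                  bestkeeper = bk$ranks, deltact = dc$ranks))
  truth <- sim$truth$tau
  geo <- cons$geomean_rank[match(names(truth), cons$gene)]
  c(consensus = cor(truth, geo, method = "spearman"),
    genorm = cor(truth, gn$ranks[names(truth)], method = "spearman"),
    normfinder = cor(truth, nf$stability[names(truth)], method = "spearman"))
}
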