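test_that("expression ratios follow efficiency-corrected delta-delta-Cq arithmetic", {
  # target drops 2 cycles, references flat, E = 1 everywhere -> R = 4
  sc <- simulate_validation_scenario(fold_change = 4, unstable_refs = 0)
  res <- expression_ratio(sc$cq, sc$target, sc$stable_refs, sc$eff)
  expect_equal(res$ratio, 4, tolerance = 1e-12)

  # single reference itself dropping 1 cycle halves the apparent ratio
  cq <- data.frame(
    gene = rep(c("t", "r"), each = 4),
    condition = rep(c("control", "control", "treatment", "treatment"), 2),
    replicate = rep(1:2, 4),
    cq = c(24, 24, 22, 22, 20, 20, 19, 19))
  res2 <- expression_ratio(cq, "t", "r", c(t = 1, r = 1))
  expect_equal(res2$ratio, 2, tolerance = 1e-12)

  # two references with fold changes 2 and 8: geometric-mean denominator 4
  cq3 <- data.frame(
    gene = rep(c("t", "r1", "r2"), each = 4),
    condition = rep(c("control", "control", "treatment", "treatment"), 3),
    replicate = rep(1:2, 6),
    cq = c(24, 24, 22, 22,  20, 20, 19, 19,  20, 20, 17, 17))
  res3 <- expression_ratio(cq3, "t", c("r1", "r2"), c(t = 1, r1 = 1, r2 = 1))
  expect_equal(res3$ratio, 1, tolerance = 1e-12)

  expect_error(expression_ratio(cq, "t", character(0), c(t = 1, r = 1)), "reference")
  expect_error(expression_ratio(cq, "t", "r", c(t = 1)), "efficiency")
})

test_that("with equal efficiencies and flat references log2 R equals ddCq", {
  set.seed(90)
  reps <- 1:3
  cq <- rbind(
    data.frame(gene = "t", condition = "control", replicate = reps, cq = 24 + rnorm(3, 0, 0.1)),
    data.frame(gene = "t", condition = "treatment", replicate = reps, cq = 21 + rnorm(3, 0, 0.1)),
    data.frame(gene = "r", condition = "control", replicate = reps, cq = 20),
    data.frame(gene = "r", condition = "treatment", replicate = reps, cq = 20))
  res <- expression_ratio(cq, "t", "r", c(t = 1, r = 1))
  ddcq <- mean(cq$cq[cq$gene == "t" & cq$condition == "control"]) -
    mean(cq$cq[cq$gene == "t" & cq$condition == "treatment"])
  expect_equal(res$log2_ratio, ddcq, tolerance = 1e-12)
})

test_that("an unstable reference biases the ratio by exactly its fold change", {
  # true 4-fold induction, unstable refs shifted +2 log2 -> apparent ratio 1
  sc <- simulate_validation_scenario(fold_change = 4, unstable_ref_shift = 2)
  biased <- expression_ratio(sc$cq, sc$target, sc$unstable_refs, sc$eff)
  expect_equal(biased$ratio, 1, tolerance = 1e-12)
  honest <- expression_ratio(sc$cq, sc$target, sc$stable_refs, sc$eff)
  expect_equal(honest$ratio, 4, tolerance = 1e-12)
})

test_that("the randomization test is seeded, deterministic, and sane under the null", {
  sc <- simulate_validation_scenario(fold_change = 1, reps = 5, noise_sd = 0.2, seed = 12)
  p1 <- randomization_test(sc$cq, sc$target, sc$stable_refs, sc$eff,
                           n_permutations = 500, seed = 99)$p_value
  p2 <- randomization_test(sc$cq, sc$target, sc$stable_refs, sc$eff,
                           n_permutations = 500, seed = 99)$p_value
  expect_identical(p1, p2)

  # treated identical to control: the null is true by construction
  cq <- data.frame(gene = rep(c("t", "r"), each = 8),
                   condition = rep(rep(c("control", "treatment"), each = 4), 2),
                   replicate = rep(1:4, 4),
                   cq = rep(c(24, 25, 23, 24), 4))
  p <- randomization_test(cq, "t", "r", c(t = 1, r = 1),
                          n_permutations = 1000, seed = 3)$p_value
  expect_gte(p, 0.5)
})

test_that("tiny designs fall back to exact enumeration with a warning", {
  sc <- simulate_validation_scenario(fold_change = 4, reps = 2, noise_sd = 0.1, seed = 4)
  expect_warning(
    res <- randomization_test(sc$cq, sc$target, sc$stable_refs, sc$eff,
                              n_permutations = 1000, seed = 5),
    "exact enumeration")
  expect_true(res$exact)
  expect_equal(res$n_permutations, choose(4, 2))
  expect_gt(res$p_value, 0)
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration within binomial error", {
  sc <- simulate_validation_scenario(fold_change = 2, reps = 3, noise_sd = 0.3, seed = 8)
  # exact p over all C(6,3) = 20 reallocations, computed by brute force
  cq <- sc$cq
  eff <- sc$eff
  reps <- unique(cq[, c("condition", "replicate")])
  z <- sapply(seq_len(nrow(reps)), function(i) {
    rows <- function(g) cq$cq[cq$gene == g & cq$condition == reps$condition[i] &
                                cq$replicate == reps$replicate[i]]
    -mean(rows(sc$target)) + mean(sapply(sc$stable_refs, function(r) mean(rows(r))))
  })
  is_trt <- reps$condition == "treatment"
  obs <- abs(mean(z[is_trt]) - mean(z[!is_trt]))
  splits <- combn(6, 3)
  perm <- apply(splits, 2, function(ix) abs(mean(z[ix]) - mean(z[-ix])))
  p_exact <- mean(perm >= obs - 1e-12)

  p_mc <- randomization_test(cq, sc$target, sc$stable_refs, eff,
                             n_permutations = 4000, seed = 17)$p_value
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000) + 2 / 4000)
})

test_that("the randomization test detects a strong induction at its granularity", {
  # a 3v3 design admits only C(6,3) = 20 distinct reallocations, so the
  # smallest attainable two-sided p is 0.1; a clear 4-fold induction should
  # sit at that floor, and a richer 5v5 design should cross alpha = 0.05
  pv3 <- sapply(1:20, function(s) {
    sc <- simulate_validation_scenario(4, reps = 3, noise_sd = 0.2, seed = 4000 + s)
    randomization_test(sc$cq, sc$target, sc$stable_refs, sc$eff,
                       n_permutations = 1000, seed = s)$p_value
  })
  expect_gte(mean(pv3 <= 0.12), 0.9)

  pv5 <- sapply(1:10, function(s) {
    sc <- simulate_validation_scenario(4, reps = 5, noise_sd = 0.2, seed = 5000 + s)
    randomization_test(sc$cq, sc$target, sc$stable_refs, sc$eff,
                       n_permutations = 1000, seed = s)$p_value
  })
  expect_gte(mean(pv5 < 0.05), 0.9)
})
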