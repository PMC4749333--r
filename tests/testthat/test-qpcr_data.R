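test_that("a simulated dataset round-trips through CSV bit-exactly", {
  sim <- simulate_cq_dataset(simulation_config(seed = 11))
  tmp <- withr::local_tempdir()
  cq_path <- file.path(tmp, "cq.csv")
  sheet_path <- file.path(tmp, "sheet.csv")
  write_cq_table(sim$dataset, cq_path, sheet_path)
  back <- read_cq_table(cq_path, sheet_path)

  expect_identical(back$genes, sim$dataset$genes)
  expect_identical(back$samples, sim$dataset$samples)
  expect_identical(back$units, sim$dataset$units)
  # CSV carries full double precision via write.csv's 15-digit default
  expect_equal(back$cq, sim$dataset$cq, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the default design matches the 20-sample study layout", {
  sim <- simulate_cq_dataset(simulation_config(seed = 1, n_bio_reps = 1))
  d <- sim$dataset
  expect_length(d$genes, 25)
  expect_length(d$samples, 20)
  sets <- sample_sets(d)
  expect_equal(lengths(sets)[c("genotypes", "stress", "tissues", "all")],
               c(genotypes = 9L, stress = 8L, tissues = 5L, all = 20L))
  # the shared control belongs to every set
  expect_true(all(vapply(sets, function(s) "JG11" %in% s, logical(1))))
  # wide file: 20 samples x 1 bio rep x 3 tech reps = 60 well columns
  tmp <- withr::local_tempfile(fileext = ".csv")
  sheet <- withr::local_tempfile(fileext = ".csv")
  write_cq_table(d, tmp, sheet)
  expect_length(read.csv(tmp, check.names = FALSE), 61)
})

test_that("malformed inputs are rejected with clear errors", {
  tmp <- withr::local_tempdir()
  sheet_path <- file.path(tmp, "sheet.csv")
  write.csv(data.frame(sample_id = "s1", bio_rep = 1, set_memberships = "all",
                       group = "g", is_control = TRUE),
            sheet_path, row.names = FALSE)

  empty <- file.path(tmp, "empty.csv")
  writeLines("gene", empty)
  expect_error(read_cq_table(empty, sheet_path), "no genes parsed")

  dup <- file.path(tmp, "dup.csv")
  writeLines(c("gene,s1__1__1", "a,20", "a,21"), dup)
  expect_error(read_cq_table(dup, sheet_path), "duplicate gene")

  out_of_range <- file.path(tmp, "oor.csv")
  writeLines(c("gene,s1__1__1", "a,55"), out_of_range)
  expect_error(read_cq_table(out_of_range, sheet_path), "gene 'a'.*unit 's1__1'")

  unmapped <- file.path(tmp, "unmapped.csv")
  writeLines(c("gene,s2__1__1", "a,20"), unmapped)
  expect_error(read_cq_table(unmapped, sheet_path), "unmapped")
})

make_tiny_dataset <- function(reps_by_gene) {
  # one sample, one bio rep, technical replicates given per gene
  genes <- names(reps_by_gene)
  n_tech <- max(lengths(reps_by_gene))
  cq <- array(NA_real_, c(length(genes), 1, n_tech),
              dimnames = list(genes, "s1__1", NULL))
  for (g in seq_along(genes)) cq[g, 1, seq_along(reps_by_gene[[g]])] <- reps_by_gene[[g]]
  cq_dataset(cq, data.frame(sample_id = "s1", bio_rep = 1, set_memberships = "all",
                            group = "g", is_control = TRUE))
}

test_that("replicate aggregation averages, tolerates missing wells, and flags noisy ones", {
  d <- make_tiny_dataset(list(a = c(20.0, 20.2, 20.1),
                              b = c(20.0, NA, 20.4),
                              c = c(20.0, 23.0, 20.1)))
  m <- aggregate_replicates(d, sd_flag_threshold = 0.5)
  expect_equal(unname(m$cq_mean["a", "s1"]), 20.1)
  expect_equal(unname(m$cq_mean["b", "s1"]), 20.2)
  expect_equal(unname(m$cq_mean["c", "s1"]), mean(c(20.0, 23.0, 20.1)))
  expect_identical(m$qc$gene, "c")
  expect_gt(m$qc$tech_sd, 0.5)
})

test_that("aggregation averages technical then biological replicates and is order-invariant", {
  genes <- c("a", "b", "c")
  cq <- array(NA_real_, c(3, 2, 2), dimnames = list(genes, c("s1__1", "s1__2"), NULL))
  cq["a", , ] <- rbind(c(20, 22), c(25, 27))  # bio means 21 and 26 -> sample mean 23.5
  cq["b", , ] <- 24
  cq["c", , ] <- rbind(c(18, NA), c(19, 21))  # bio means 18 and 20 -> 19
  sheet <- data.frame(sample_id = "s1", bio_rep = 1:2, set_memberships = "all",
                      group = "g", is_control = TRUE)
  m <- aggregate_replicates(cq_dataset(cq, sheet))
  expect_equal(unname(m$cq_mean[, "s1"]), c(23.5, 24, 19))
  expect_equal(unname(m$rep_sd["a", "s1"]), sd(c(21, 26)))

  # permuting technical replicates changes nothing
  m2 <- aggregate_replicates(cq_dataset(cq[, , 2:1], sheet))
  expect_equal(m2$cq_mean, m$cq_mean)
})

test_that("a fully missing cell is left missing with a warning", {
  genes <- c("a", "b")
  cq <- array(NA_real_, c(2, 1, 2), dimnames = list(genes, "s1__1", NULL))
  cq["b", 1, ] <- c(20, 20)
  d <- cq_dataset(cq, data.frame(sample_id = "s1", bio_rep = 1, set_memberships = "all",
                                 group = "g", is_control = TRUE))
  expect_warning(m <- aggregate_replicates(d), "left missing")
  expect_true(is.na(m$cq_mean["a", "s1"]))
})

test_that("descriptive statistics match hand-computed mean and CV", {
  cqm <- structure(list(genes = c("flat", "two"), samples = c("s1", "s2", "s3"),
                        cq_mean = rbind(flat = c(20, 20, 20), two = c(19, 21, NA)),
                        rep_sd = NULL, qc = data.frame()),
                   class = "cq_matrix")
  st <- descriptive_stats(cqm)
  expect_equal(st$mean_cq, c(20, 20))
  expect_equal(st$cv_percent[st$gene == "flat"], 0)
  # SD of (19, 21) is sqrt(2); CV% = 100 * sqrt(2) / 20
  expect_equal(st$cv_percent[st$gene == "two"], 100 * sqrt(2) / 20, tolerance = 1e-12)
  expect_equal(st$min_cq, c(20, 19))
  expect_equal(st$max_cq, c(20, 21))

  # permutation invariance and shift consistency
  cqm2 <- cqm
  cqm2$cq_mean <- cqm$cq_mean[, c(3, 1, 2)]
  expect_equal(descriptive_stats(cqm2)[, -1], st[, -1])
  cqm3 <- cqm
  cqm3$cq_mean["two", ] <- cqm$cq_mean["two", ] + 5
  st3 <- descriptive_stats(cqm3)
  expect_equal(st3$mean_cq[2], 25)
  expect_equal(st3$cv_percent[2], 100 * sqrt(2) / 25, tolerance = 1e-12)
})

test_that("set membership validation enforces the superset structure", {
  cq <- array(20, c(3, 2, 1), dimnames = list(c("a", "b", "c"), c("s1__1", "s2__1"), NULL))
  bad_sheet <- data.frame(sample_id = c("s1", "s2"), bio_rep = 1,
                          set_memberships = c("stress", "all"),
                          group = "g", is_control = FALSE)
  expect_error(cq_dataset(cq, bad_sheet), "superset")
  good <- bad_sheet
  good$set_memberships <- c("stress;all", "all")
  expect_s3_class(cq_dataset(cq, good), "cq_dataset")
})
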