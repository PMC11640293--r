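write_long_report <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("DIA report pivots to a matrix and never zero-fills", {
  long <- data.frame(Run = c("r1", "r2", "r3", "r1", "r2"),
                     Protein.Group = c("A", "A", "A", "B", "B"),
                     PG.MaxLFQ = c(1, 2, 3, 4, 5))
  mat <- read_dia_report(write_long_report(long))
  expect_equal(dim(mat), c(2L, 3L))
  expect_equal(mat["A", ], c(r1 = 1, r2 = 2, r3 = 3))
  # absent (protein, run) pair stays missing, not 0
  expect_true(is.na(mat["B", "r3"]))

  dup <- rbind(long, long[1, ])
  expect_error(read_dia_report(write_long_report(dup)), "duplicated")

  bad <- long; names(bad)[3] <- "Other"
  expect_error(read_dia_report(write_long_report(bad)), "PG.MaxLFQ")
})

test_that("median normalization equalizes run medians and spares missing", {
  set.seed(31)
  mat <- matrix(2^rnorm(60, mean = 20), 10, 6,
                dimnames = list(sprintf("P%02d", 1:10), sprintf("r%d", 1:6)))
  mat[sample(60, 8)] <- NA
  out <- normalize_median(mat)
  med <- apply(log2(out), 2, median, na.rm = TRUE)
  expect_equal(max(med) - min(med), 0, tolerance = 1e-9)
  # missing cells stay missing, observed cells stay observed
  expect_identical(is.na(out), is.na(mat))

  # a table whose run medians are already equal is unchanged
  eq <- matrix(2^c(1, 2, 3, 1, 2, 3), 3, 2)
  expect_equal(normalize_median(eq), eq, tolerance = 1e-9)

  # a +1 log2-unit shift of a run is removed exactly (shift the run with
  # the largest median so the grand median of run medians is unchanged)
  shifted <- mat
  top <- which.max(apply(log2(mat), 2, median, na.rm = TRUE))
  shifted[, top] <- shifted[, top] * 2
  out2 <- normalize_median(shifted)
  expect_equal(out2, out, tolerance = 1e-9)

  allna <- mat; allna[, 3] <- NA
  expect_error(normalize_median(allna), "no observed values")
  neg <- mat; neg[1, 1] <- 0
  expect_error(normalize_median(neg), "non-positive")
})

test_that("Welch's test matches reference values and symmetries", {
  sym <- welch_test(c(2, 4, 6), c(2, 4, 6))
  expect_equal(sym$t_stat, 0)
  expect_equal(sym$p_value, 1)

  w <- welch_test(c(10, 11, 12), c(20, 21, 22))
  expect_equal(w$t_stat, -12.247, tolerance = 1e-3)
  expect_equal(w$df, 4, tolerance = 1e-6)
  expect_equal(w$p_value, 2.57e-4, tolerance = 1e-2)

  flip <- welch_test(c(20, 21, 22), c(10, 11, 12))
  expect_equal(flip$t_stat, -w$t_stat)
  expect_equal(flip$p_value, w$p_value)

  expect_true(welch_test(c(1), c(2, 3, 4))$untestable)
  expect_true(welch_test(c(5, 5, 5), c(7, 7, 7))$untestable)
  expect_false(welch_test(c(5, 5, 5), c(7, 7, 8))$untestable)
})

test_that("Welch's test agrees with the closed-form oracle", {
  set.seed(32)
  for (i in 1:200) {
    x <- rnorm(sample(2:8, 1), sd = runif(1, 0.1, 3))
    y <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2),
               sd = runif(1, 0.1, 3))
    got <- welch_test(x, y)
    ref <- oracle_welch(x, y)
    expect_equal(got$t_stat, ref$t, tolerance = 1e-10)
    expect_equal(got$df, ref$df, tolerance = 1e-10)
    expect_equal(got$p_value, ref$p, tolerance = 1e-10)
  }
})

test_that("volcano classification applies thresholds and exclusivity", {
  # AltProt thresholds (p < 0.05, |log2fc| > 1)
  expect_equal(classify_differential(1.5, 0.03, 4, 4, 0.05, 1), "up_in_group1")
  # the same protein under the stricter canonical thresholds (p < 0.01)
  expect_equal(classify_differential(1.5, 0.03, 4, 4, 0.01, 1),
               "not_significant")
  expect_equal(classify_differential(-1.5, 0.03, 4, 4, 0.05, 1),
               "up_in_group2")
  # boundary: p or fc exactly at the cut is not significant (strict >/<)
  expect_equal(classify_differential(1, 0.03, 4, 4, 0.05, 1),
               "not_significant")
  expect_equal(classify_differential(1.5, 0.05, 4, 4, 0.05, 1),
               "not_significant")
  # presence/absence calls
  expect_equal(classify_differential(NA, NA, 4, 0, 0.05, 1, min_n = 3),
               "exclusive_group1")
  expect_equal(classify_differential(NA, NA, 0, 3, 0.05, 1, min_n = 3),
               "exclusive_group2")
  expect_equal(classify_differential(NA, NA, 2, 0, 0.05, 1, min_n = 3),
               "untestable")
  expect_equal(classify_differential(NA, NA, 1, 4, 0.05, 1, min_n = 3),
               "untestable")

  # every protein gets exactly one class
  set.seed(33)
  cls <- classify_differential(rnorm(100), runif(100),
                               sample(0:5, 100, TRUE), sample(0:5, 100, TRUE))
  expect_true(all(cls %in% c("up_in_group1", "up_in_group2",
                             "not_significant", "exclusive_group1",
                             "exclusive_group2", "untestable")))
  expect_length(cls, 100L)
})

test_that("the pipeline never imputes: missing cells stay missing end to end", {
  d <- make_dia_report(seed = 41, n_proteins = 60, missing_rate = 0.2)
  mat <- pivot_dia_report(d$report)
  expect_identical(is.na(mat[rownames(d$mat), colnames(d$mat)]),
                   is.na(d$mat))
  norm <- normalize_median(mat)
  expect_identical(is.na(norm), is.na(mat))
  dd <- dia_differential(mat, d$groups, numerator = "pancreatic")
  r <- as.data.frame(dd)
  expect_equal(r$n_group1 + r$n_group2,
               rowSums(!is.na(mat))[r$accession], ignore_attr = TRUE)
})

test_that("differential analysis recovers planted effects and exclusives", {
  d <- make_dia_report(seed = 42, n_proteins = 120, sigma = 0.25,
                       missing_mode = "group_exclusive", n_exclusive = 5)
  mat <- pivot_dia_report(d$report)
  dd <- dia_differential(mat, d$groups, numerator = "pancreatic")
  r <- as.data.frame(dd)
  truth <- d$truth[match(r$accession, d$truth$accession), ]

  expect_setequal(r$accession[r$class == "exclusive_group1"],
                  truth$accession[truth$exclusive])

  up <- truth$delta > 0 & !truth$exclusive
  expect_gt(mean(r$class[up] == "up_in_group1"), 0.8)
  dn <- truth$delta < 0 & !truth$exclusive
  expect_gt(mean(r$class[dn] == "up_in_group2"), 0.8)
  null <- truth$delta == 0 & !truth$exclusive
  expect_lt(mean(r$class[null] %in% c("up_in_group1", "up_in_group2")), 0.05)

  # noiseless, effect-free report: all fold changes are exactly zero and
  # nothing is testable (both group variances vanish)
  d0 <- make_dia_report(seed = 43, n_proteins = 20, sigma = 0,
                        effect_sizes = 0, effect_props = 1, missing_rate = 0)
  dd0 <- dia_differential(pivot_dia_report(d0$report), d0$groups,
                          numerator = "pancreatic", normalize = FALSE)
  r0 <- as.data.frame(dd0)
  expect_equal(r0$log2fc, rep(0, 20), tolerance = 1e-12)
  expect_true(all(r0$class == "untestable"))
})
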