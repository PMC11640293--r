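#' Read a DIA-NN-style long-format quantification report
#'
#' Pivots a long table (one row per protein group per run) into a protein
#' group x run intensity matrix. A (protein, run) pair absent from the
#' report stays missing (`NA`) — never zero-filled — in keeping with the
#' no-imputation policy of the workflow.
#'
#' @param path Path to the tab-separated report.
#' @param quantity_column Name of the quantity column (default
#'   `"PG.MaxLFQ"`).
#' @return A numeric matrix, rows = protein groups, columns = runs, with
#'   `NA` for missing cells.
#' @export
read_dia_report <- function(path, quantity_column = "PG.MaxLFQ") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  long <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("Run", "Protein.Group", quantity_column)
  missing <- setdiff(needed, names(long))
  if (length(missing))
    stop("DIA report missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  pivot_dia_report(long, quantity_column)
}

#' Pivot an in-memory long-format report to a matrix
#'
#' Same contract as [read_dia_report()] but starting from a data frame with
#' columns `Run`, `Protein.Group` and the quantity column.
#'
#' @param long Long-format data frame.
#' @param quantity_column Name of the quantity column.
#' @return A protein group x run matrix with `NA` for missing cells.
#' @export
pivot_dia_report <- function(long, quantity_column = "PG.MaxLFQ") {
  key <- paste(long$Protein.Group, long$Run, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (protein group, run) row: ",
         sub("\r", " / ", key[duplicated(key)][1]), call. = FALSE)
  q <- long[[quantity_column]]
  if (any(!is.na(q) & q < 0))
    stop("negative intensity in quantity column", call. = FALSE)
  pgs <- unique(long$Protein.Group)
  runs <- unique(long$Run)
  mat <- matrix(NA_real_, length(pgs), length(runs),
                dimnames = list(pgs, runs))
  mat[cbind(match(long$Protein.Group, pgs), match(long$Run, runs))] <- q
  mat
}

#' Median normalization of a quantification matrix
#'
#' On the log2 scale, subtracts each run's median of observed values and
#' adds back the grand median of the run medians, so all run medians become
#' equal while the overall intensity scale is preserved. Missing cells are
#' untouched. `method = "quantile"` instead applies quantile normalization
#' (via limma) on the log2 scale.
#'
#' @param mat Intensity matrix (linear scale, rows = protein groups,
#'   columns = runs, `NA` = missing). All observed values must be positive.
#' @param method `"median"` (default) or `"quantile"`.
#' @return The normalized matrix, same shape, linear scale.
#' @export
normalize_median <- function(mat, method = c("median", "quantile")) {
  method <- match.arg(method)
  if (any(!is.na(mat) & mat <= 0))
    stop("non-positive intensities cannot be log-normalized", call. = FALSE)
  nobs <- colSums(!is.na(mat))
  if (any(nobs == 0L))
    stop("run with no observed values: ",
         colnames(mat)[which(nobs == 0L)[1]], call. = FALSE)
  lg <- log2(mat)
  if (method == "median") {
    med <- apply(lg, 2L, median, na.rm = TRUE)
    lg <- sweep(lg, 2L, med) + median(med)
  } else {
    if (!requireNamespace("limma", quietly = TRUE))
      stop("quantile normalization requires the 'limma' package",
           call. = FALSE)
    lg <- limma::normalizeQuantiles(lg)
  }
  2^lg
}

#' Welch's two-sample t-test
#'
#' The unequal-variance two-sample location test with Welch--Satterthwaite
#' degrees of freedom and a two-sided p-value, as used for all differential
#' comparisons in the workflow. Computed via [stats::t.test()]. Groups with
#' fewer than two observed values, or two groups both of zero variance, are
#' untestable (no p-value, flag set).
#'
#' @param x,y Numeric vectors of observed values (NAs dropped).
#' @return A list with `t_stat`, `df`, `p_value`, `n1`, `n2`, `untestable`.
#' @examples
#' welch_test(c(10, 11, 12), c(20, 21, 22))
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L || (var(x) == 0 && var(y) == 0))
    return(list(t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
                n1 = n1, n2 = n2, untestable = TRUE))
  tt <- t.test(x, y, var.equal = FALSE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n1 = n1, n2 = n2, untestable = FALSE)
}

#' Volcano classification of a differential result
#'
#' Applies the volcano thresholds: a protein is up in group 1 when
#' `p < p_cut` and `log2fc > fc_cut`, up in group 2 when `p < p_cut` and
#' `log2fc < -fc_cut` (symmetric rule). A protein observed in at least
#' `min_n` runs of one group and zero runs of the other is called exclusive
#' to that group — a presence/absence difference that no fold change can
#' express under a no-imputation policy. Proteins with fewer than two
#' observed values in either group (and not exclusive) are untestable.
#'
#' @param log2fc,p_value Numeric vectors.
#' @param n1,n2 Observed counts per group.
#' @param p_cut,fc_cut Thresholds (e.g. 0.05 and 1 for AltProts, 0.01 and 1
#'   for the canonical proteome).
#' @param min_n Minimum observations for an exclusivity call (default 3, in
#'   line with 3--4 replicates per cell line).
#' @return A character vector over `{up_in_group1, up_in_group2,
#'   not_significant, exclusive_group1, exclusive_group2, untestable}`;
#'   every input falls in exactly one class.
#' @export
classify_differential <- function(log2fc, p_value, n1, n2,
                                  p_cut = 0.05, fc_cut = 1, min_n = 3L) {
  if (p_cut <= 0 || fc_cut <= 0)
    stop("thresholds must be positive", call. = FALSE)
  n <- length(log2fc)
  stopifnot(length(p_value) == n, length(n1) == n, length(n2) == n)
  out <- rep("not_significant", n)
  testable <- n1 >= 2L & n2 >= 2L & !is.na(p_value)
  out[testable & p_value < p_cut & log2fc > fc_cut] <- "up_in_group1"
  out[testable & p_value < p_cut & log2fc < -fc_cut] <- "up_in_group2"
  out[!testable] <- "untestable"
  out[n1 >= min_n & n2 == 0L] <- "exclusive_group1"
  out[n2 >= min_n & n1 == 0L] <- "exclusive_group2"
  out
}

#' Two-group differential analysis of a DIA quantification matrix
#'
#' The quantitative core of the workflow: median normalization (optional),
#' per-protein Welch's t-test on log2 intensities of observed values (no
#' imputation), fold changes as the log2 ratio of linear-scale group means
#' of observed values, volcano classification, and presence/absence
#' (exclusivity) calls. Raw Welch p-values gate the volcano classes, as in
#' the original analysis; a Benjamini--Hochberg column is reported for
#' information only.
#'
#' @param mat Intensity matrix from [read_dia_report()] (linear scale).
#' @param groups Named character vector or factor: group label per run
#'   (names = column names of `mat`); exactly two levels.
#' @param numerator The group treated as group 1 (the fold-change
#'   numerator); default: first level.
#' @param normalize Apply [normalize_median()] first (default `TRUE`).
#' @param p_cut,fc_cut,min_n Classification thresholds, see
#'   [classify_differential()].
#' @return An object of class `"dia_diff"` wrapping a results data frame
#'   (`accession`, `n_group1`, `n_group2`, `mean_group1`, `mean_group2`,
#'   `log2fc`, `t_stat`, `df`, `p_value`, `bh_fdr`, `class`) with
#'   `print()`, `summary()`, `plot()` (volcano) and `as.data.frame()`
#'   methods.
#' @export
dia_differential <- function(mat, groups, numerator = NULL,
                             normalize = TRUE, p_cut = 0.05, fc_cut = 1,
                             min_n = 3L) {
  if (!is.null(names(groups))) {
    groups <- groups[colnames(mat)]
  } else if (length(groups) != ncol(mat)) {
    stop("'groups' must be named by run or have one label per column",
         call. = FALSE)
  }
  if (anyNA(groups))
    stop("'groups' must name every run (column) of the matrix",
         call. = FALSE)
  lv <- unique(as.character(groups))
  if (length(lv) != 2L)
    stop("exactly two group labels are required, got: ",
         paste(lv, collapse = ", "), call. = FALSE)
  if (is.null(numerator)) numerator <- lv[1]
  if (!numerator %in% lv)
    stop("'numerator' is not one of the group labels", call. = FALSE)
  g1 <- colnames(mat)[as.character(groups) == numerator]
  g2 <- setdiff(colnames(mat), g1)
  if (normalize) mat <- normalize_median(mat)

  res <- lapply(rownames(mat), function(acc) {
    x <- mat[acc, g1]; y <- mat[acc, g2]
    xo <- x[!is.na(x)]; yo <- y[!is.na(y)]
    wt <- welch_test(log2(xo), log2(yo))
    m1 <- if (length(xo)) mean(xo) else NA_real_
    m2 <- if (length(yo)) mean(yo) else NA_real_
    data.frame(accession = acc, n_group1 = length(xo), n_group2 = length(yo),
               mean_group1 = m1, mean_group2 = m2,
               log2fc = log2(m1 / m2),
               t_stat = wt$t_stat, df = wt$df, p_value = wt$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$bh_fdr <- p.adjust(res$p_value, method = "BH")
  res$class <- classify_differential(res$log2fc, res$p_value,
                                     res$n_group1, res$n_group2,
                                     p_cut, fc_cut, min_n)
  structure(list(results = res, group1 = numerator,
                 group2 = setdiff(lv, numerator),
                 p_cut = p_cut, fc_cut = fc_cut, min_n = min_n,
                 normalized = normalize),
            class = "dia_diff")
}

#' @export
print.dia_diff <- function(x, ...) {
  tab <- table(factor(x$results$class,
                      levels = c("up_in_group1", "up_in_group2",
                                 "exclusive_group1", "exclusive_group2",
                                 "not_significant", "untestable")))
  cat("Two-group DIA differential analysis (Welch's t-test, no imputation)\n")
  cat("  group 1: ", x$group1, "   group 2: ", x$group2, "\n", sep = "")
  cat(sprintf("  thresholds: p < %g, |log2 fold change| > %g\n",
              x$p_cut, x$fc_cut))
  cat("  ", nrow(x$results), " protein groups:\n", sep = "")
  for (cl in names(tab)) cat(sprintf("    %-18s %d\n", cl, tab[[cl]]))
  invisible(x)
}

#' @export
summary.dia_diff <- function(object, ...) {
  r <- object$results
  structure(list(
    n = nrow(r),
    classes = table(r$class),
    n_tested = sum(!is.na(r$p_value)),
    median_log2fc = median(r$log2fc, na.rm = TRUE),
    thresholds = c(p = object$p_cut, fc = object$fc_cut),
    groups = c(object$group1, object$group2)
  ), class = "summary.dia_diff")
}

#' @export
print.summary.dia_diff <- function(x, ...) {
  cat("DIA differential summary: ", x$n, " protein groups, ", x$n_tested,
      " testable\n", sep = "")
  cat("  median log2 fold change: ", round(x$median_log2fc, 3), "\n", sep = "")
  print(x$classes)
  invisible(x)
}

#' @export
as.data.frame.dia_diff <- function(x, ...) x$results

#' Volcano plot of a differential analysis
#'
#' @param x A `"dia_diff"` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dia_diff <- function(x, ...) {
  r <- x$results[!is.na(x$results$p_value), ]
  col <- ifelse(r$class == "up_in_group1", "#2166ac",
         ifelse(r$class == "up_in_group2", "#b2182b", "grey60"))
  plot(r$log2fc, -log10(r$p_value), pch = 16, cex = 0.6, col = col,
       xlab = sprintf("log2(%s / %s)", x$group1, x$group2),
       ylab = expression(-log[10] ~ italic(p)), ...)
  abline(v = c(-x$fc_cut, x$fc_cut), h = -log10(x$p_cut),
         lty = 2, col = "grey40")
  legend("topleft", bty = "n", pch = 16, col = c("#2166ac", "#b2182b"),
         legend = c(paste("up in", x$group1), paste("up in", x$group2)))
  invisible(x)
}
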