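#' Net charge of a polypeptide at a given pH
#'
#' Henderson--Hasselbalch model over nine ionizable groups: the N-terminus
#' and side chains of K, R, H contribute `+1 / (1 + 10^(pH - pKa))` each;
#' the C-terminus and side chains of D, E, C, Y contribute
#' `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param sequence A single amino-acid string (standard residues).
#' @param pH Numeric vector of pH values.
#' @param pka_set Name of a set in [pka_sets] or a compatible list.
#' @return Net charge, one value per element of `pH`.
#' @export
net_charge <- function(sequence, pH, pka_set = "emboss") {
  counts <- .ionizable_counts(sequence)
  pka <- .resolve_pka(pka_set)
  vapply(pH, function(p) .charge_at(counts, p, pka), numeric(1))
}

.resolve_pka <- function(pka_set) {
  if (is.character(pka_set)) {
    if (!pka_set %in% names(pka_sets))
      stop("unknown pKa set '", pka_set, "'; available: ",
           paste(names(pka_sets), collapse = ", "), call. = FALSE)
    pka_sets[[pka_set]]
  } else pka_set
}

# counts matrix row for one sequence: (K, R, H, D, E, C, Y); termini implied
.ionizable_counts <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (any(chars == "X"))
    stop("cannot compute charge for a sequence containing 'X'",
         call. = FALSE)
  if (any(!chars %in% AA_LETTERS))
    stop("invalid residue '", chars[!chars %in% AA_LETTERS][1], "'",
         call. = FALSE)
  vapply(c("K", "R", "H", "D", "E", "C", "Y"),
         function(a) sum(chars == a), numeric(1))
}

.charge_at <- function(counts, pH, pka) {
  pos_n <- c(nterm = 1, counts[c("K", "R", "H")])
  neg_n <- c(cterm = 1, counts[c("D", "E", "C", "Y")])
  names(pos_n) <- names(pka$pos)
  names(neg_n) <- names(pka$neg)
  sum(pos_n / (1 + 10^(pH - pka$pos))) - sum(neg_n / (1 + 10^(pka$neg - pH)))
}

#' Isoelectric point of polypeptides
#'
#' The pH at which the Henderson--Hasselbalch net charge is zero, found by
#' bisection on `[0, 14]` to a tolerance of 1e-4 pH units. The net-charge
#' function is strictly decreasing in pH and bracketed on that interval
#' (the termini are always present), so the root exists and is unique. The
#' pKa set is pluggable because published sets disagree by up to ~0.5 pH
#' units; `"emboss"` is the default.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @param pka_set Name of a set in [pka_sets] or a compatible list.
#' @param tol Bisection tolerance in pH units.
#' @return Numeric vector of pI values.
#' @examples
#' isoelectric_point(c("DDD", "KKK"))
#' @export
isoelectric_point <- function(sequences, pka_set = "emboss", tol = 1e-4) {
  pka <- .resolve_pka(pka_set)
  counts <- t(vapply(sequences, .ionizable_counts, numeric(7)))
  colnames(counts) <- c("K", "R", "H", "D", "E", "C", "Y")
  pos_n <- cbind(nterm = 1, counts[, c("K", "R", "H"), drop = FALSE])
  neg_n <- cbind(cterm = 1, counts[, c("D", "E", "C", "Y"), drop = FALSE])
  charge_at <- function(pH) {
    # pH: vector, one per sequence
    pos <- sapply(seq_along(pka$pos), function(j)
      pos_n[, j] / (1 + 10^(pH - pka$pos[j])))
    neg <- sapply(seq_along(pka$neg), function(j)
      neg_n[, j] / (1 + 10^(pka$neg[j] - pH)))
    if (is.null(dim(pos))) sum(pos) - sum(neg)
    else rowSums(pos) - rowSums(neg)
  }
  lo <- rep(0, length(sequences)); hi <- rep(14, length(sequences))
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    pos_charge <- charge_at(mid) > 0
    lo[pos_charge] <- mid[pos_charge]
    hi[!pos_charge] <- mid[!pos_charge]
  }
  unname((lo + hi) / 2)
}

#' Profile the physicochemical properties and origins of AltProts
#'
#' Computes, over the AltProt/Isoform records of a database: the amino-acid
#' length distribution (bins of 50 aa by default), the isoelectric-point
#' distribution (bins of 1 pH unit over \[3, 13) with open outer bins), the
#' RNA-source class proportions, and the median length and pI. Records
#' containing `X` are dropped from the pI computation with a warning.
#'
#' @param db A `"protein_db"` (or a record data frame); only altprot and
#'   isoform records are profiled, and RNA-source metadata must be complete.
#' @param length_bin Length bin width in amino acids.
#' @param pi_range Inner range for the pI histogram.
#' @param pka_set Passed to [isoelectric_point()].
#' @return An object of class `"profile_summary"`: list with `n`, `table`
#'   (per-record data frame: `accession`, `length`, `pi`, `source`),
#'   `median_length`, `median_pi`, `length_bins`, `pi_bins`,
#'   `source_proportions`.
#' @export
summarize_profiles <- function(db, length_bin = 50L, pi_range = c(3, 13),
                               pka_set = "emboss") {
  rec <- db[db$category %in% c("altprot", "isoform"), , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no altprot/isoform records to profile", call. = FALSE)
  src <- .rna_source_vec(rec$category, rec$biotype, rec$orf_location)
  if (anyNA(src))
    stop("unclassifiable record '", rec$accession[which(is.na(src))[1]],
         "': missing or inconsistent RNA-source metadata", call. = FALSE)
  len <- nchar(rec$sequence)
  pi_ok <- !rec$has_x
  if (any(!pi_ok))
    warning(sum(!pi_ok), " record(s) containing 'X' excluded from pI",
            call. = FALSE)
  pi <- rep(NA_real_, nrow(rec))
  pi[pi_ok] <- isoelectric_point(rec$sequence[pi_ok], pka_set = pka_set)

  len_breaks <- seq(0, ceiling(max(len) / length_bin) * length_bin,
                    by = length_bin)
  length_bins <- table(cut(len, len_breaks, right = TRUE,
                           include.lowest = FALSE))
  pi_breaks <- c(-Inf, seq(pi_range[1], pi_range[2]), Inf)
  pi_bins <- table(cut(pi[pi_ok], pi_breaks, right = FALSE))

  src_levels <- c("uORF", "intORF", "dORF", "lncRNA", "misc_RNA",
                  "novel_isoform")
  props <- table(factor(src, levels = src_levels)) / length(src)

  structure(list(
    n = nrow(rec),
    table = data.frame(accession = rec$accession, length = len, pi = pi,
                       source = src, stringsAsFactors = FALSE),
    median_length = median(len),
    median_pi = median(pi, na.rm = TRUE),
    length_bins = length_bins,
    pi_bins = pi_bins,
    source_proportions = c(props)
  ), class = "profile_summary")
}

#' @export
print.profile_summary <- function(x, ...) {
  cat("<profile_summary> ", x$n, " AltProt/Isoform records\n", sep = "")
  cat(sprintf("  median length: %.1f aa   median pI: %.2f\n",
              x$median_length, x$median_pi))
  cat("  RNA-source proportions:\n")
  for (s in names(x$source_proportions))
    cat(sprintf("    %-14s %.1f%%\n", s, 100 * x$source_proportions[[s]]))
  invisible(x)
}

#' Write a profile summary to JSON
#'
#' Medians, histogram bins and source proportions, suitable for downstream
#' reporting.
#'
#' @param x A `"profile_summary"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_profile_summary <- function(x, path) {
  jsonlite::write_json(list(
    n = x$n,
    median_length = x$median_length,
    median_pi = x$median_pi,
    length_bins = as.list(x$length_bins),
    pi_bins = as.list(x$pi_bins),
    source_proportions = as.list(x$source_proportions)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
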