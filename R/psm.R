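#' Annotate a PSM: match theoretical b/y ions to observed peaks
#'
#' Each theoretical b/y fragment ion (indices 1..n-1, the given charges) is
#' matched to the nearest observed peak within `tol_ppm`; on an exact tie the
#' lower-m/z peak wins, so the result is deterministic and independent of
#' input peak order. A peak may satisfy several theoretical ions, but each
#' ion matches at most one peak. The backbone-coverage fraction is computed
#' from the matched ions (see [coverage_fraction()]).
#'
#' @param spectrum A spectrum list ([read_mgf()] element).
#' @param pep Peptide or notation string.
#' @param tol_ppm Match tolerance in ppm (default 20, appropriate for HCD
#'   Orbitrap MS2 at 15,000 resolution).
#' @param charges Fragment charges to consider.
#' @param coverage_method `"site"` (default) or `"residue"`, see
#'   [coverage_fraction()].
#' @return An object of class `"annotated_psm"`: a list with `spectrum_id`,
#'   `peptide` (notation), `peptide_length`, `precursor_charge`,
#'   `matched_ions` (data frame: `series`, `index`, `charge`, `mz_theo`,
#'   `peak`, `mz_obs`, `intensity`, `ppm_error`), `coverage`, `n_matched`,
#'   `proteotypic` and `validated` (both `NA` until set).
#' @export
match_fragments <- function(spectrum, pep, tol_ppm = 20, charges = c(1L, 2L),
                            coverage_method = c("site", "residue")) {
  coverage_method <- match.arg(coverage_method)
  if (tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  pep <- parse_peptide(pep)
  n <- nchar(pep$sequence)
  theo <- enumerate_fragments(pep, charges)
  peaks <- spectrum$peaks
  o <- order(peaks$mz)
  peaks <- peaks[o, , drop = FALSE]
  if (nrow(peaks)) {
    idx <- findInterval(theo$mz, peaks$mz)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, nrow(peaks))
    err_lo <- abs(peaks$mz[lo] - theo$mz) / theo$mz * 1e6
    err_hi <- abs(peaks$mz[hi] - theo$mz) / theo$mz * 1e6
    # tie (equal ppm error) -> lower m/z candidate
    use_lo <- err_lo <= err_hi
    best <- ifelse(use_lo, lo, hi)
    best_err <- ifelse(use_lo, err_lo, err_hi)
    hit <- best_err <= tol_ppm
  } else {
    hit <- logical(nrow(theo))
  }
  matched <- data.frame(
    series = theo$series[hit], index = theo$index[hit],
    charge = theo$charge[hit], mz_theo = theo$mz[hit],
    peak = if (any(hit)) best[hit] else integer(),
    mz_obs = if (any(hit)) peaks$mz[best[hit]] else numeric(),
    intensity = if (any(hit)) peaks$intensity[best[hit]] else numeric(),
    ppm_error = if (any(hit)) (peaks$mz[best[hit]] - theo$mz[hit]) /
      theo$mz[hit] * 1e6 else numeric(),
    stringsAsFactors = FALSE
  )
  structure(
    list(spectrum_id = spectrum$spectrum_id,
         peptide = peptide_notation(pep),
         peptide_length = n,
         precursor_charge = spectrum$precursor_charge,
         parent_accessions = pep$parent_accessions,
         matched_ions = matched,
         coverage = coverage_fraction(matched, n, method = coverage_method),
         n_matched = nrow(matched),
         proteotypic = NA, validated = NA),
    class = "annotated_psm"
  )
}

#' @export
print.annotated_psm <- function(x, ...) {
  cat("<annotated_psm> ", x$spectrum_id, "  ", x$peptide,
      sprintf("  coverage %.3f (%d ions)\n", x$coverage, x$n_matched),
      sep = "")
  invisible(x)
}

#' Backbone-coverage fraction of a matched-ion set
#'
#' A length-n peptide has n-1 inter-residue fragmentation sites. A b ion of
#' index i evidences site i; a y ion of index j evidences site n-j. The
#' default coverage is the fraction of distinct sites evidenced by at least
#' one matched b or y ion (complementary b/y pairs count their shared site
#' once). The alternative `"residue"` method counts residues spanned by the
#' matched fragments (b_i spans residues 1..i, y_j spans n-j+1..n) over n.
#'
#' @param matched_ions Data frame with `series` and `index` columns.
#' @param peptide_length Peptide length n (must be >= 2).
#' @param method `"site"` or `"residue"`.
#' @return A fraction in `[0, 1]`.
#' @examples
#' ions <- data.frame(series = c("b", "y"), index = c(1, 1))
#' coverage_fraction(ions, 3)    # sites {1, 2} of 2 -> 1.0
#' @export
coverage_fraction <- function(matched_ions, peptide_length,
                              method = c("site", "residue")) {
  method <- match.arg(method)
  n <- as.integer(peptide_length)
  if (n < 2L) stop("peptide length must be >= 2", call. = FALSE)
  if (is.null(matched_ions) || nrow(matched_ions) == 0L) return(0)
  if (method == "site") {
    sites <- ifelse(matched_ions$series == "b",
                    matched_ions$index, n - matched_ions$index)
    length(unique(sites)) / (n - 1L)
  } else {
    covered <- logical(n)
    b <- matched_ions$index[matched_ions$series == "b"]
    y <- matched_ions$index[matched_ions$series == "y"]
    if (length(b)) covered[seq_len(max(b))] <- TRUE
    if (length(y)) covered[(n - max(y) + 1L):n] <- TRUE
    sum(covered) / n
  }
}

#' Partition PSMs by the fragment-coverage filter
#'
#' Keeps PSMs whose y/b backbone coverage is at least `threshold`
#' (inclusive: a PSM at exactly the threshold is kept). The default 0.75
#' reflects the stringent curation applied to AltProt identifications, where
#' a protein is often evidenced by a single peptide.
#'
#' @param psms List of `"annotated_psm"` objects.
#' @param threshold Coverage threshold in `(0, 1]`.
#' @return A list with elements `kept` and `rejected`; their union is the
#'   input and they are disjoint.
#' @export
apply_coverage_filter <- function(psms, threshold = 0.75) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  cov <- vapply(psms, function(p) p$coverage, numeric(1))
  list(kept = psms[cov >= threshold], rejected = psms[cov < threshold])
}

#' Proteotypicity screen by substring search
#'
#' A peptide is proteotypic when its sequence occurs in exactly one protein
#' of the search space, so its detection uniquely evidences that protein.
#' Isoleucine and leucine are indistinguishable by mass, so they are
#' collapsed by default before the scan.
#'
#' @param pep Peptide or notation string (modifications are ignored).
#' @param db A `"protein_db"`.
#' @param target Optional accession(s) the PSM claims; if given, the peptide
#'   must occur in the claimed parent (else an inconsistent-PSM error).
#' @param il_equivalent Collapse I and L before matching (default `TRUE`).
#' @return A list with `proteotypic` (logical) and `hits` (character vector
#'   of all accessions containing the peptide).
#' @export
check_proteotypicity <- function(pep, db, target = NULL,
                                 il_equivalent = TRUE) {
  seqpep <- strip_peptide(pep)
  seqs <- db$sequence
  if (il_equivalent) {
    seqpep <- chartr("I", "L", seqpep)
    seqs <- chartr("I", "L", seqs)
  }
  hits <- db$accession[grepl(seqpep, seqs, fixed = TRUE)]
  if (!is.null(target) && length(target) && !all(target %in% hits))
    stop("inconsistent PSM: peptide '", strip_peptide(pep),
         "' absent from claimed parent ",
         paste(setdiff(target, hits), collapse = ";"), call. = FALSE)
  proteotypic <- length(hits) == 1L &&
    (is.null(target) || identical(sort(unique(as.character(target))), hits))
  list(proteotypic = proteotypic, hits = hits)
}

#' Read a PSM table
#'
#' Tab-separated with columns `spectrum_id`, `peptide` (inline-tag
#' notation), `charge` and `accessions` (semicolon-separated).
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_psm_table <- function(path) {
  psms <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("spectrum_id", "peptide", "charge", "accessions")
  missing <- setdiff(needed, names(psms))
  if (length(missing))
    stop("PSM table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  psms
}

#' Curate a PSM table against spectra and a database
#'
#' Runs the full curation pipeline: fragment annotation and backbone
#' coverage per PSM, the >= `min_coverage` filter, and the proteotypicity
#' screen. Manual validation is out of scope for software; the `validated`
#' column can be imported from a reviewer TSV afterwards.
#'
#' @param spectra List of spectra ([read_mgf()]).
#' @param psm_table Data frame from [read_psm_table()].
#' @param db A `"protein_db"`.
#' @param tol_ppm,charges,coverage_method Passed to [match_fragments()].
#' @param min_coverage Coverage threshold for the filter.
#' @param il_equivalent Passed to [check_proteotypicity()].
#' @return A list with `psms` (list of `"annotated_psm"`, proteotypic flag
#'   set) and `report`, a data frame with one row per PSM: `spectrum_id`,
#'   `peptide`, `charge`, `accessions`, `coverage`, `matched_ion_count`,
#'   `proteotypic`, `hit_accessions`, `kept`.
#' @export
curate_psms <- function(spectra, psm_table, db, tol_ppm = 20,
                        charges = c(1L, 2L), min_coverage = 0.75,
                        il_equivalent = TRUE,
                        coverage_method = c("site", "residue")) {
  coverage_method <- match.arg(coverage_method)
  sp_ids <- vapply(spectra, function(s) s$spectrum_id, "")
  idx <- match(psm_table$spectrum_id, sp_ids)
  if (anyNA(idx))
    stop("PSM references unknown spectrum: ",
         psm_table$spectrum_id[which(is.na(idx))[1]], call. = FALSE)
  psms <- vector("list", nrow(psm_table))
  proteo <- logical(nrow(psm_table))
  hits_str <- character(nrow(psm_table))
  for (i in seq_len(nrow(psm_table))) {
    pep <- parse_peptide(psm_table$peptide[i])
    accs <- strsplit(psm_table$accessions[i], ";", fixed = TRUE)[[1]]
    pep$parent_accessions <- accs
    psm <- match_fragments(spectra[[idx[i]]], pep, tol_ppm, charges,
                           coverage_method)
    pt <- check_proteotypicity(pep, db, target = accs,
                               il_equivalent = il_equivalent)
    psm$proteotypic <- pt$proteotypic
    proteo[i] <- pt$proteotypic
    hits_str[i] <- paste(pt$hits, collapse = ";")
    psms[[i]] <- psm
  }
  cov <- vapply(psms, function(p) p$coverage, numeric(1))
  report <- data.frame(
    spectrum_id = psm_table$spectrum_id,
    peptide = psm_table$peptide,
    charge = psm_table$charge,
    accessions = psm_table$accessions,
    coverage = cov,
    matched_ion_count = vapply(psms, function(p) p$n_matched, numeric(1)),
    proteotypic = proteo,
    hit_accessions = hits_str,
    kept = cov >= min_coverage,
    stringsAsFactors = FALSE
  )
  list(psms = psms, report = report)
}
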