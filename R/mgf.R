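#' Read an MGF peak-list file
#'
#' Parses Mascot Generic Format: `BEGIN IONS`/`END IONS` blocks with
#' `PEPMASS` (required), `CHARGE`, `TITLE` and `RTINSECONDS` headers followed
#' by `m/z intensity` peak lines. Peaks are returned sorted by m/z. Blocks
#' lacking `CHARGE` default to 2+ with a warning (tryptic peptides are
#' predominantly doubly charged).
#'
#' @param path Path to an MGF file.
#' @return A list of spectra; each spectrum is a list with `spectrum_id`,
#'   `precursor_mz`, `precursor_charge`, `rt` (seconds, `NA` if absent) and
#'   `peaks`, a data frame with columns `mz`, `intensity` sorted by `mz`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path,
         call. = FALSE)
  spectra <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    lineno <- (begins[k] + 1L):(ends[k] - 1L)
    is_hdr <- grepl("^[A-Z][A-Z0-9]*=", block)
    hdr <- block[is_hdr]
    keys <- sub("=.*$", "", hdr)
    vals <- sub("^[^=]*=", "", hdr)
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    pepmass <- getv("PEPMASS")
    if (is.na(pepmass))
      stop("MGF block at line ", begins[k], " is missing PEPMASS",
           call. = FALSE)
    precursor_mz <- suppressWarnings(as.numeric(strsplit(pepmass, "\\s+")[[1]][1]))
    if (is.na(precursor_mz))
      stop("unparseable PEPMASS at line ",
           lineno[is_hdr][match("PEPMASS", keys)], call. = FALSE)
    ch <- getv("CHARGE")
    if (is.na(ch)) {
      warning("MGF block at line ", begins[k],
              " has no CHARGE; defaulting to 2+", call. = FALSE)
      charge <- 2L
    } else {
      charge <- suppressWarnings(as.integer(sub("\\+$", "", ch)))
      if (is.na(charge) || charge < 1L)
        stop("unparseable CHARGE at line ",
             lineno[is_hdr][match("CHARGE", keys)], call. = FALSE)
    }
    title <- getv("TITLE")
    rtsec <- suppressWarnings(as.numeric(getv("RTINSECONDS")))
    peak_lines <- block[!is_hdr & nzchar(trimws(block))]
    peak_lineno <- lineno[!is_hdr & nzchar(trimws(block))]
    if (length(peak_lines)) {
      fields <- strsplit(trimws(peak_lines), "\\s+")
      nf <- lengths(fields)
      if (any(nf < 1L | nf > 3L))
        stop("malformed peak line at line ", peak_lineno[which(nf < 1L | nf > 3L)[1]],
             call. = FALSE)
      mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
      inten <- suppressWarnings(as.numeric(vapply(fields, function(f)
        if (length(f) >= 2L) f[2] else "1", "")))
      if (anyNA(mz) || anyNA(inten))
        stop("non-numeric peak value at line ",
             peak_lineno[which(is.na(mz) | is.na(inten))[1]], call. = FALSE)
      if (any(inten < 0))
        stop("negative intensity at line ",
             peak_lineno[which(inten < 0)[1]], call. = FALSE)
      o <- order(mz)
      peaks <- data.frame(mz = mz[o], intensity = inten[o])
    } else {
      peaks <- data.frame(mz = numeric(), intensity = numeric())
    }
    spectra[[k]] <- list(
      spectrum_id = if (is.na(title)) sprintf("spectrum_%d", k) else title,
      precursor_mz = precursor_mz, precursor_charge = charge,
      rt = rtsec, peaks = peaks
    )
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra A list of spectra as returned by [read_mgf()] or
#'   [make_spectra()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", sp$precursor_charge), con)
    if (!is.null(sp$rt) && !is.na(sp$rt))
      writeLines(sprintf("RTINSECONDS=%.3f", sp$rt), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.6f %.4f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
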