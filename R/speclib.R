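# Column dialect accepted by DIA-NN as a library input (OpenSWATH-style TSV)
LIBRARY_COLUMNS <- c(
  "PrecursorMz", "ProductMz", "Annotation", "ProteinId", "GeneName",
  "PeptideSequence", "ModifiedPeptideSequence", "PrecursorCharge",
  "LibraryIntensity", "NormalizedRetentionTime", "FragmentType",
  "FragmentSeriesNumber", "FragmentCharge"
)

#' Build a spectral library from curated PSMs
#'
#' One library entry per (modified peptide, precursor charge). When several
#' PSMs map to the same precursor, the one with the highest backbone
#' coverage wins, ties broken by matched-ion count then lexicographic
#' spectrum id, so the result is fully deterministic. Fragment intensities
#' come from the matched peaks and are renormalized to a maximum of 1 within
#' each precursor. Retention times are rescaled linearly to a 0--100
#' normalized axis (`iRT`) over `rt_range` (default: the span of the
#' supplied retention times).
#'
#' @param psms List of `"annotated_psm"` objects that passed the coverage
#'   filter (and, for AltProts, the proteotypicity screen).
#' @param rt Named numeric vector: retention time (minutes) per spectrum id.
#' @param rt_range Length-2 numeric, the run's retention-time span used for
#'   the linear 0--100 rescale; defaults to `range(rt)`.
#' @param min_fragments Minimum fragment rows per precursor; entries below
#'   the floor are dropped with a warning.
#' @return A data frame of class `"spectral_library"`, one row per fragment,
#'   with the DIA-NN-compatible columns (see [write_library_tsv()]).
#' @export
build_library <- function(psms, rt, rt_range = NULL, min_fragments = 3L) {
  if (!length(psms)) stop("no PSMs supplied", call. = FALSE)
  ids <- vapply(psms, function(p) p$spectrum_id, "")
  if (anyNA(match(ids, names(rt))))
    stop("missing retention time for spectrum ",
         ids[which(is.na(match(ids, names(rt))))[1]], call. = FALSE)
  if (is.null(rt_range)) rt_range <- range(rt, na.rm = TRUE)
  span <- rt_range[2] - rt_range[1]
  if (span <= 0) stop("degenerate retention-time range", call. = FALSE)

  has_ions <- vapply(psms, function(p) p$n_matched > 0L, logical(1))
  if (any(!has_ions)) {
    warning(sum(!has_ions), " PSM(s) without matched ions skipped",
            call. = FALSE)
    psms <- psms[has_ions]
  }
  if (!length(psms)) stop("no PSMs with matched ions", call. = FALSE)

  key <- vapply(psms, function(p)
    paste(p$peptide, p$precursor_charge, sep = "/"), "")
  cov <- vapply(psms, function(p) p$coverage, numeric(1))
  nm <- vapply(psms, function(p) p$n_matched, numeric(1))
  sid <- vapply(psms, function(p) p$spectrum_id, "")
  ord <- order(key, -cov, -nm, sid)
  keep <- ord[!duplicated(key[ord])]

  rows <- vector("list", length(keep))
  dropped <- 0L
  for (j in seq_along(keep)) {
    p <- psms[[keep[j]]]
    if (p$n_matched < min_fragments) { dropped <- dropped + 1L; next }
    pep <- parse_peptide(p$peptide)
    ions <- p$matched_ions
    irt <- (rt[[p$spectrum_id]] - rt_range[1]) / span * 100
    rows[[j]] <- data.frame(
      PrecursorMz = precursor_mz(pep, p$precursor_charge),
      ProductMz = ions$mz_theo,
      Annotation = sprintf("%s%d^%d", ions$series, ions$index, ions$charge),
      ProteinId = paste(pep$parent_accessions, collapse = ";"),
      GeneName = "",
      PeptideSequence = pep$sequence,
      ModifiedPeptideSequence = p$peptide,
      PrecursorCharge = p$precursor_charge,
      LibraryIntensity = ions$intensity / max(ions$intensity),
      NormalizedRetentionTime = irt,
      FragmentType = ions$series,
      FragmentSeriesNumber = ions$index,
      FragmentCharge = ions$charge,
      stringsAsFactors = FALSE
    )
  }
  if (dropped)
    warning(dropped, " precursor(s) below the ", min_fragments,
            "-fragment floor dropped", call. = FALSE)
  lib <- do.call(rbind, rows)
  if (is.null(lib)) stop("no library entries survive the fragment floor",
                         call. = FALSE)
  rownames(lib) <- NULL
  class(lib) <- c("spectral_library", "data.frame")
  attr(lib, "irt_scheme") <- "linear0-100"
  lib
}

#' Write / read the DIA-NN-compatible library TSV
#'
#' Tab-separated, one row per fragment ion, with the exact header
#' `PrecursorMz  ProductMz  Annotation  ProteinId  GeneName
#' PeptideSequence  ModifiedPeptideSequence  PrecursorCharge
#' LibraryIntensity  NormalizedRetentionTime  FragmentType
#' FragmentSeriesNumber  FragmentCharge` (OpenSWATH-style TSV, accepted by
#' DIA-NN as a library input). A leading `#irt=linear0-100` comment records
#' the retention-time convention. `read_library_tsv()` is the exact inverse
#' and accepts any column order, erroring with the list of missing columns
#' otherwise.
#'
#' @param lib A `"spectral_library"` data frame.
#' @param path File path.
#' @return `write_library_tsv()` returns `path` invisibly;
#'   `read_library_tsv()` returns the library data frame.
#' @export
write_library_tsv <- function(lib, path) {
  missing <- setdiff(LIBRARY_COLUMNS, names(lib))
  if (length(missing))
    stop("library is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#irt=", attr(lib, "irt_scheme") %||% "linear0-100"), con)
  write.table(as.data.frame(lib)[LIBRARY_COLUMNS], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  irt_scheme <- if (startsWith(first, "#irt=")) sub("^#irt=", "", first)
                else "linear0-100"
  lib <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  missing <- setdiff(LIBRARY_COLUMNS, names(lib))
  if (length(missing))
    stop("library TSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lib <- lib[LIBRARY_COLUMNS]
  for (col in c("PrecursorMz", "ProductMz", "LibraryIntensity",
                "NormalizedRetentionTime"))
    lib[[col]] <- as.numeric(lib[[col]])
  for (col in c("PrecursorCharge", "FragmentSeriesNumber", "FragmentCharge"))
    lib[[col]] <- as.integer(lib[[col]])
  class(lib) <- c("spectral_library", "data.frame")
  attr(lib, "irt_scheme") <- irt_scheme
  lib
}

#' Staggered DIA isolation-window scheme
#'
#' Pass 1 tiles `[lo, hi)` with contiguous windows of the given width
#' (`ceiling((hi - lo) / width)` windows). With a non-zero offset a second,
#' interleaved pass shifted by `+offset` is added — the staggered-window
#' design that improves effective precursor selectivity. The workflow's
#' acquisition scheme, 2 passes of 75 windows of 8 m/z staggered by 4 m/z
#' over 400--1000 m/z, is `make_window_scheme(400, 1000, 8, 4)`.
#'
#' @param lo,hi Precursor m/z range (Th), `hi > lo`.
#' @param width Window width (Th), > 0.
#' @param offset Stagger offset (Th), `0 <= offset < width`; 0 gives a
#'   single pass.
#' @return An object of class `"window_scheme"`: list with `passes` (list of
#'   data frames with `lower`, `upper`), `width`, `offset`, `range`.
#' @examples
#' ws <- make_window_scheme(400, 1000, 8, 4)
#' length(ws$passes)        # 2
#' nrow(ws$passes[[1]])     # 75
#' @export
make_window_scheme <- function(lo, hi, width, offset = 0) {
  if (hi <= lo) stop("'hi' must exceed 'lo'", call. = FALSE)
  if (width <= 0) stop("'width' must be positive", call. = FALSE)
  if (offset < 0 || offset >= width)
    stop("'offset' must satisfy 0 <= offset < width", call. = FALSE)
  n <- ceiling((hi - lo) / width)
  lower1 <- lo + (seq_len(n) - 1) * width
  pass1 <- data.frame(lower = lower1, upper = lower1 + width)
  passes <- list(pass1)
  if (offset > 0)
    passes[[2]] <- data.frame(lower = lower1 + offset,
                              upper = lower1 + offset + width)
  structure(list(passes = passes, width = width, offset = offset,
                 range = c(lo, hi)),
            class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat("<window_scheme> ", length(x$passes), " pass(es) x ",
      nrow(x$passes[[1]]), " windows, width ", x$width, " m/z, offset ",
      x$offset, " m/z over [", x$range[1], ", ", x$range[2], ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.window_scheme <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$passes), function(p) {
    w <- x$passes[[p]]
    data.frame(pass = p, index = seq_len(nrow(w)),
               lower_mz = w$lower, upper_mz = w$upper)
  }))
}

#' Export a window scheme as TSV
#'
#' Columns `pass`, `index`, `lower_mz`, `upper_mz`.
#'
#' @param scheme A `"window_scheme"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_scheme <- function(scheme, path) {
  write.table(as.data.frame(scheme), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
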