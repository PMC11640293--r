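#' Construct a peptide with modifications
#'
#' A peptide is an amino-acid sequence plus a (possibly empty) set of
#' positional modifications. Position 0 denotes the N-terminus (e.g. protein
#' N-terminal acetylation); positions 1..n modify the corresponding residue.
#' At most one modification per position.
#'
#' @param sequence Uppercase amino-acid string (standard 20 letters; `X` is
#'   accepted by the parser but rejected by all mass operations).
#' @param mod_pos Integer vector of modification positions (0 = N-terminus).
#' @param mod_delta Numeric vector of monoisotopic delta masses (Da), one per
#'   position in `mod_pos`.
#' @param missed_cleavages Number of internal missed cleavage sites.
#' @param parent_accessions Character vector of accessions of the proteins
#'   the peptide maps to.
#' @return An object of class `"peptide"`.
#' @seealso [parse_peptide()], [peptide_notation()]
#' @export
peptide <- function(sequence, mod_pos = integer(), mod_delta = numeric(),
                    missed_cleavages = 0L, parent_accessions = character()) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a single non-empty string", call. = FALSE)
  sequence <- toupper(sequence)
  bad <- !strsplit(sequence, "")[[1]] %in% c(AA_LETTERS, "X")
  if (any(bad))
    stop("invalid residue at position ", which(bad)[1], " in '", sequence, "'",
         call. = FALSE)
  mod_pos <- as.integer(mod_pos)
  if (length(mod_pos) != length(mod_delta))
    stop("'mod_pos' and 'mod_delta' lengths differ", call. = FALSE)
  if (length(mod_pos)) {
    if (any(mod_pos < 0L | mod_pos > nchar(sequence)))
      stop("modification position out of [0, peptide length]", call. = FALSE)
    if (anyDuplicated(mod_pos))
      stop("at most one modification per position", call. = FALSE)
    if (any(!is.finite(mod_delta)))
      stop("modification delta mass must be finite", call. = FALSE)
    o <- order(mod_pos)
    mod_pos <- mod_pos[o]; mod_delta <- mod_delta[o]
  }
  structure(
    list(sequence = sequence, mod_pos = mod_pos, mod_delta = mod_delta,
         missed_cleavages = as.integer(missed_cleavages),
         parent_accessions = as.character(parent_accessions)),
    class = "peptide"
  )
}

#' Parse inline-tag peptide notation
#'
#' The notation used in PSM tables and spectral libraries carries
#' modifications as bracketed mass tags after the modified residue, e.g.
#' `"AC[+57.02146]K"`; an N-terminal modification is a leading tag followed
#' by a dash, e.g. `"[+42.01057]-MKR"`. Deltas are signed decimal Da values.
#'
#' @param x A notation string, or an existing `"peptide"` object (returned
#'   unchanged).
#' @return A `"peptide"` object.
#' @examples
#' parse_peptide("AC[+57.02146]K")
#' parse_peptide("[+42.01057]-MK")
#' @export
parse_peptide <- function(x) {
  if (inherits(x, "peptide")) return(x)
  if (!is.character(x) || length(x) != 1L)
    stop("expected a single peptide notation string", call. = FALSE)
  if (!nzchar(x))
    stop("peptide notation must be non-empty", call. = FALSE)
  s <- x
  mod_pos <- integer(); mod_delta <- numeric()
  nterm <- regmatches(s, regexec("^\\[([+-]?[0-9]*\\.?[0-9]+)\\]-", s))[[1]]
  if (length(nterm)) {
    mod_pos <- 0L
    mod_delta <- as.numeric(nterm[2])
    s <- substring(s, nchar(nterm[1]) + 1L)
  }
  toks <- regmatches(s, gregexpr("([A-Z])(\\[[+-]?[0-9]*\\.?[0-9]+\\])?", s))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != s)
    stop("malformed peptide notation: '", x, "'", call. = FALSE)
  res <- substr(toks, 1L, 1L)
  has_tag <- nchar(toks) > 1L
  if (any(has_tag)) {
    deltas <- as.numeric(sub("^[A-Z]\\[([+-]?[0-9]*\\.?[0-9]+)\\]$", "\\1",
                             toks[has_tag]))
    mod_pos <- c(mod_pos, which(has_tag))
    mod_delta <- c(mod_delta, deltas)
  }
  peptide(paste(res, collapse = ""), mod_pos, mod_delta)
}

#' Render a peptide in inline-tag notation
#'
#' Inverse of [parse_peptide()]: deltas are printed signed with five decimal
#' places, which round-trips all standard modification masses bit-exactly.
#'
#' @param pep A `"peptide"` object or notation string.
#' @return A single string.
#' @examples
#' peptide_notation(peptide("ACK", mod_pos = 2, mod_delta = 57.02146))
#' @export
peptide_notation <- function(pep) {
  pep <- parse_peptide(pep)
  tag <- function(d) sprintf("[%+.5f]", d)
  res <- strsplit(pep$sequence, "")[[1]]
  out <- res
  for (i in seq_along(pep$mod_pos)) {
    p <- pep$mod_pos[i]
    if (p > 0L) out[p] <- paste0(out[p], tag(pep$mod_delta[i]))
  }
  body <- paste(out, collapse = "")
  if (length(pep$mod_pos) && pep$mod_pos[1] == 0L)
    body <- paste0(tag(pep$mod_delta[1]), "-", body)
  body
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", peptide_notation(x), "\n", sep = "")
  if (length(x$parent_accessions))
    cat("  parents: ", paste(x$parent_accessions, collapse = ";"), "\n", sep = "")
  invisible(x)
}

#' Apply fixed modifications to a peptide
#'
#' Adds each fixed modification in `mods` (default: carbamidomethylation of
#' cysteine) to every matching, not-yet-modified site.
#'
#' @param pep Peptide or notation string.
#' @param mods Modification table as returned by [standard_modifications()].
#' @return A `"peptide"` object.
#' @export
apply_fixed_modifications <- function(pep, mods = standard_modifications()) {
  pep <- parse_peptide(pep)
  fixed <- mods[mods$fixed & startsWith(mods$site, "residue:"), , drop = FALSE]
  for (i in seq_len(nrow(fixed))) {
    res <- sub("^residue:", "", fixed$site[i])
    pos <- which(strsplit(pep$sequence, "")[[1]] == res)
    pos <- setdiff(pos, pep$mod_pos)
    if (length(pos))
      pep <- peptide(pep$sequence,
                     c(pep$mod_pos, pos),
                     c(pep$mod_delta, rep(fixed$delta_mass[i], length(pos))),
                     pep$missed_cleavages, pep$parent_accessions)
  }
  pep
}

# bare residue string (modification tags removed)
strip_peptide <- function(x) parse_peptide(x)$sequence
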