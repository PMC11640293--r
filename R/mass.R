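#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after K or R, by default not before proline
#' (the classical trypsin rule used by Mascot). Products with up to
#' `missed_cleavages_max` internal missed cleavage sites are returned,
#' filtered to `length_range`. With zero missed cleavages and no length
#' filter, the products concatenate back to the input sequence.
#'
#' @param sequence Protein sequence (standard residues only; `X` is an
#'   error because its mass is undefined).
#' @param missed_cleavages_max Maximum number of internal missed cleavages.
#' @param length_range Numeric length 2, inclusive peptide-length bounds.
#' @param proline_rule If `TRUE` (default), K/R followed by P is not cleaved.
#' @return A data frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`.
#' @examples
#' digest("AAKRCC")$sequence                 # "AAK" "R" "CC"
#' digest("AAKPRC")$sequence                 # "AAKPR" "C"  (proline rule)
#' digest("AAKRCC", missed_cleavages_max = 1)$sequence
#' @export
digest <- function(sequence, missed_cleavages_max = 0L,
                   length_range = c(1, Inf), proline_rule = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a single non-empty string", call. = FALSE)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (any(chars == "X"))
    stop("undigestible residue 'X' at position ", which(chars == "X")[1],
         call. = FALSE)
  bad <- !chars %in% AA_LETTERS
  if (any(bad))
    stop("invalid residue '", chars[which(bad)[1]], "' at position ",
         which(bad)[1], call. = FALSE)
  n <- length(chars)
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts < n]
  if (proline_rule && length(cuts))
    cuts <- cuts[chars[cuts + 1L] != "P"]
  ends <- c(cuts, n)
  starts <- c(1L, head(ends, -1L) + 1L)
  k <- length(starts)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    jmax <- min(k, i + missed_cleavages_max)
    js <- i:jmax
    out[[i]] <- data.frame(
      sequence = substring(sequence, starts[i], ends[js]),
      start = starts[i], end = ends[js], missed_cleavages = js - i,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  len <- nchar(res$sequence)
  res <- res[len >= length_range[1] & len <= length_range[2], , drop = FALSE]
  rownames(res) <- NULL
  res
}

# residue masses of a peptide object; errors on X/unknown
.residue_masses <- function(pep) {
  chars <- strsplit(pep$sequence, "")[[1]]
  m <- AA_MONO[chars]
  if (anyNA(m))
    stop("unknown or massless residue '", chars[which(is.na(m))[1]],
         "' at position ", which(is.na(m))[1], call. = FALSE)
  unname(m)
}

#' Monoisotopic neutral mass of a (modified) peptide
#'
#' Sum of monoisotopic residue masses plus one water plus all modification
#' delta masses.
#'
#' @param pep A `"peptide"` object or inline-tag notation string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_neutral_mass("AG")               # 146.06914
#' peptide_neutral_mass("C[+57.02146]")     # carbamidomethyl-Cys
#' @export
peptide_neutral_mass <- function(pep) {
  pep <- parse_peptide(pep)
  sum(.residue_masses(pep)) + WATER_MONO + sum(pep$mod_delta)
}

#' Precursor m/z of a peptide
#'
#' @param pep Peptide or notation string.
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @export
precursor_mz <- function(pep, charge = 2L) {
  if (charge < 1L) stop("charge must be >= 1", call. = FALSE)
  (peptide_neutral_mass(pep) + charge * PROTON_MONO) / charge
}

#' b/y fragment-ion m/z
#'
#' b ions retain the first `index` residues from the N-terminus (plus any
#' N-terminal modification); y ions retain the last `index` residues plus
#' water. The singly charged ion adds one proton; higher charges divide.
#'
#' @param pep Peptide or notation string.
#' @param series `"b"` or `"y"`.
#' @param index Fragment index, vectorized; `1 <= index <= length`. The
#'   full-length b_n/y_n ions are computable here, but backbone
#'   fragmentation only produces indices up to `length - 1`, which is all
#'   [enumerate_fragments()] emits.
#' @param charge Positive integer charge.
#' @return Numeric vector of m/z values (Th).
#' @examples
#' fragment_mz("AG", "b", 1)   # b1 = immonium-side fragment of A
#' fragment_mz("AGK", "y", 1)  # y1 of K: 147.11281
#' @export
fragment_mz <- function(pep, series = c("b", "y"), index, charge = 1L) {
  series <- match.arg(series)
  pep <- parse_peptide(pep)
  n <- nchar(pep$sequence)
  index <- as.integer(index)
  if (any(index < 1L | index > n))
    stop("fragment index out of range [1, ", n, "]", call. = FALSE)
  if (charge < 1L) stop("charge must be >= 1", call. = FALSE)
  rm_ <- .residue_masses(pep)
  moddelta <- numeric(n + 1L)                   # slot 1 = position 0 (N-term)
  if (length(pep$mod_pos)) moddelta[pep$mod_pos + 1L] <- pep$mod_delta
  if (series == "b") {
    prefix <- cumsum(rm_) + cumsum(moddelta[-1L]) + moddelta[1L]
    neutral <- prefix[index]
  } else {
    rev_res <- rev(rm_)
    rev_mod <- rev(moddelta[-1L])               # N-term mod never on y ions
    suffix <- cumsum(rev_res) + cumsum(rev_mod)
    neutral <- suffix[index] + WATER_MONO
  }
  (neutral + charge * PROTON_MONO) / charge
}

#' Enumerate all b/y fragment ions of a peptide
#'
#' @param pep Peptide or notation string.
#' @param charges Set of fragment charges, subset of `{1, 2}` by default.
#' @return A data frame with columns `series`, `index`, `charge`, `mz`;
#'   `2 * (n - 1) * length(charges)` rows for a length-n peptide.
#' @export
enumerate_fragments <- function(pep, charges = c(1L, 2L)) {
  pep <- parse_peptide(pep)
  n <- nchar(pep$sequence)
  if (n < 2L) stop("peptide too short to fragment", call. = FALSE)
  charges <- sort(unique(as.integer(charges)))
  grid <- expand.grid(index = seq_len(n - 1L), series = c("b", "y"),
                      charge = charges, stringsAsFactors = FALSE)
  mz <- numeric(nrow(grid))
  for (s in c("b", "y")) for (z in charges) {
    sel <- grid$series == s & grid$charge == z
    mz[sel] <- fragment_mz(pep, s, grid$index[sel], z)
  }
  data.frame(series = grid$series, index = grid$index,
             charge = grid$charge, mz = mz, stringsAsFactors = FALSE)
}
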