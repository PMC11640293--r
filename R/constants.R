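# Monoisotopic masses (Da). Residue masses are the standard amino-acid
# residue (i.e. dehydrated) monoisotopic values; peptide neutral mass adds
# one water. Proton mass is used for m/z charging.

AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

WATER_MONO  <- 18.010565
PROTON_MONO <- 1.007276

AA_LETTERS <- names(AA_MONO)

#' Standard peptide modifications
#'
#' The three modifications used throughout the workflow: carbamidomethylation
#' of cysteine (fixed, from alkylation), oxidation of methionine (variable)
#' and acetylation of the protein N-terminus (variable). Delta masses are
#' monoisotopic (Unimod values).
#'
#' @return A data frame with columns `name`, `delta_mass` (Da), `site`
#'   (`"residue:C"`, `"residue:M"` or `"protein_n_term"`) and `fixed`.
#' @examples
#' standard_modifications()
#' @export
standard_modifications <- function() {
  data.frame(
    name       = c("carbamidomethyl", "oxidation", "acetyl"),
    delta_mass = c(57.02146, 15.99491, 42.01057),
    site       = c("residue:C", "residue:M", "protein_n_term"),
    fixed      = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' pKa sets for isoelectric-point computation
#'
#' Named list of pKa tables for the nine ionizable groups used by the
#' Henderson--Hasselbalch net-charge model: the two termini plus D, E, C, Y
#' (acidic) and H, K, R (basic). Published sets disagree by up to ~0.5 pH
#' units, so the set is pluggable; `"emboss"` is the default.
#'
#' @format A list with elements `emboss` and `bjellqvist`; each element is a
#'   list with numeric vectors `pos` (N-terminus, K, R, H) and `neg`
#'   (C-terminus, D, E, C, Y).
#' @examples
#' pka_sets$emboss
#' @export
pka_sets <- list(
  emboss = list(
    pos = c(nterm = 8.6,  K = 10.8, R = 12.5, H = 6.5),
    neg = c(cterm = 3.6,  D = 3.9,  E = 4.1,  C = 8.5, Y = 10.1)
  ),
  bjellqvist = list(
    pos = c(nterm = 7.5,  K = 10.0, R = 12.0, H = 5.98),
    neg = c(cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  )
)

# approximate vertebrate amino-acid background frequencies, used by the
# synthetic-proteome generator
AA_FREQ <- c(
  A = 0.074, R = 0.042, N = 0.044, D = 0.059, C = 0.033, Q = 0.037,
  E = 0.058, G = 0.074, H = 0.029, I = 0.038, L = 0.076, K = 0.072,
  M = 0.018, F = 0.040, P = 0.050, S = 0.081, T = 0.062, W = 0.013,
  Y = 0.033, V = 0.068
)
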