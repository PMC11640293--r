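# Independent oracles used to cross-check the package implementation.
# These deliberately avoid the code paths they verify: masses are summed
# from elemental compositions, Welch's statistic from the closed form, and
# proteotypicity from an all-substrings scan.

# residue elemental compositions (C, H, N, O, S)
RESIDUE_FORMULA <- rbind(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)
ATOM_MONO <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
               O = 15.9949146196, S = 31.97207100)
ORACLE_WATER <- 2 * ATOM_MONO[["H"]] + ATOM_MONO[["O"]]
ORACLE_PROTON <- 1.00727646688

oracle_formula_mass <- function(counts) sum(counts * ATOM_MONO)

oracle_residue_sum <- function(residues) {
  if (!length(residues)) return(0)
  sum(vapply(residues, function(r)
    oracle_formula_mass(RESIDUE_FORMULA[r, ]), numeric(1)))
}

# neutral monoisotopic mass of a modified peptide, from atoms up
oracle_peptide_mass <- function(pep) {
  pep <- parse_peptide(pep)
  res <- strsplit(pep$sequence, "")[[1]]
  oracle_residue_sum(res) + ORACLE_WATER + sum(pep$mod_delta)
}

# b/y fragment m/z from elemental composition of the retained residues
oracle_fragment_mz <- function(pep, series, index, charge = 1) {
  pep <- parse_peptide(pep)
  res <- strsplit(pep$sequence, "")[[1]]
  n <- length(res)
  deltas <- numeric(n + 1)
  if (length(pep$mod_pos)) deltas[pep$mod_pos + 1] <- pep$mod_delta
  if (series == "b") {
    neutral <- oracle_residue_sum(res[seq_len(index)]) +
      sum(deltas[1:(index + 1)])
  } else {
    keep <- (n - index + 1):n
    neutral <- oracle_residue_sum(res[keep]) + sum(deltas[keep + 1]) +
      ORACLE_WATER
  }
  (neutral + charge * ORACLE_PROTON) / charge
}

# closed-form Welch two-sample t-test (textbook formulas + t CDF)
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x) / n1; v2 <- var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force proteotypicity: enumerate every substring of every protein
oracle_hits <- function(pep, db, il_equivalent = TRUE) {
  pep <- if (il_equivalent) chartr("I", "L", pep) else pep
  k <- nchar(pep)
  hit <- vapply(seq_len(nrow(db)), function(i) {
    s <- db$sequence[i]
    if (il_equivalent) s <- chartr("I", "L", s)
    L <- nchar(s)
    if (L < k) return(FALSE)
    pep %in% substring(s, 1:(L - k + 1), k:L)
  }, logical(1))
  db$accession[hit]
}

random_sequence <- function(len) {
  paste(sample(rownames(RESIDUE_FORMULA), len, replace = TRUE),
        collapse = "")
}

# random peptide, optionally modified (carbamidomethyl-C always; sometimes
# oxidized M, sometimes N-terminal acetyl)
random_peptide <- function(len = sample(6:20, 1), modify = TRUE) {
  seqs <- random_sequence(len)
  pep <- peptide(seqs)
  if (modify) {
    pep <- apply_fixed_modifications(pep)
    mpos <- setdiff(which(strsplit(seqs, "")[[1]] == "M"), pep$mod_pos)
    if (length(mpos) && runif(1) < 0.5)
      pep <- peptide(seqs, c(pep$mod_pos, mpos[1]),
                     c(pep$mod_delta, 15.99491))
    if (runif(1) < 0.3 && !0L %in% pep$mod_pos)
      pep <- peptide(seqs, c(pep$mod_pos, 0L), c(pep$mod_delta, 42.01057))
  }
  pep
}
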