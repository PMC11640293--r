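Package: altprotcurator
Title: Curation, Spectral Library Construction and Quantification of
    Alternative Proteins from Mass Spectrometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the mass-spectrometry-driven study of alternative
    proteins (AltProts), the products of unannotated open reading frames on
    lncRNAs, UTRs and out-of-frame CDS regions. Reads and merges canonical,
    OpenProt-style AltProt/Isoform and contaminant FASTA databases; performs
    in-silico tryptic digestion and monoisotopic b/y fragment-ion mass
    arithmetic; curates peptide-spectrum matches by backbone fragment-ion
    coverage and proteotypicity; builds DIA-NN-compatible spectral libraries
    and staggered DIA isolation-window schemes; and post-processes DIA
    quantification reports with median normalization and Welch's t-test
    differential analysis without imputation. A synthetic fixture generator
    produces fully ground-truthed FASTA, MGF, PSM and DIA inputs for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
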