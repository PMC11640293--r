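#' Read a protein FASTA into categorized records
#'
#' Headers are split at the first whitespace into accession and description.
#' Sequences are uppercased and validated: the 20 standard amino acids plus
#' `X` (unknown residue) are accepted; records containing `X` are flagged in
#' the `has_x` column and excluded from digestion/mass operations downstream.
#'
#' Category follows the OpenProt accession convention: in an `"openprot"`
#' file, accessions starting `IP_` are alternative proteins (altprot) and
#' `II_` are novel isoforms; a file read as `"canonical"` or
#' `"contaminant"` must not contain such accessions.
#'
#' @param path Path to a FASTA file.
#' @param category One of `"canonical"`, `"contaminant"`, `"openprot"` (the
#'   mixed AltProt/Isoform database), or `"altprot"`/`"isoform"` to force a
#'   single class.
#' @return A data frame with columns `accession`, `description`, `sequence`,
#'   `category`, `has_x`.
#' @seealso [merge_databases()], [write_fasta()]
#' @export
read_fasta <- function(path,
                       category = c("canonical", "contaminant", "openprot",
                                    "altprot", "isoform")) {
  category <- match.arg(category)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(accession)))
    stop("FASTA entry with empty header in ", path, call. = FALSE)
  dup <- accession[duplicated(accession)]
  if (length(dup))
    stop("duplicate accession in ", path, ": ", dup[1], call. = FALSE)
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i]))
      stop("empty sequence for accession ", accession[i], call. = FALSE)
    bad <- regexpr(sprintf("[^%sX]", paste(AA_LETTERS, collapse = "")), seqs[i])
    if (bad > 0L)
      stop("non-amino-acid character '", substr(seqs[i], bad, bad),
           "' at position ", bad, " in accession ", accession[i],
           call. = FALSE)
  }
  cat_of <- function(acc) {
    is_ip <- startsWith(acc, "IP_")
    is_ii <- startsWith(acc, "II_")
    if (category == "openprot") {
      if (!all(is_ip | is_ii))
        stop("accession without IP_/II_ prefix in openprot file: ",
             acc[!(is_ip | is_ii)][1], call. = FALSE)
      ifelse(is_ip, "altprot", "isoform")
    } else {
      expected <- switch(category, altprot = is_ip, isoform = is_ii,
                         !(is_ip | is_ii))
      if (!all(expected))
        stop("accession prefix inconsistent with category '", category,
             "': ", acc[!expected][1], call. = FALSE)
      rep(category, length(acc))
    }
  }
  data.frame(
    accession = unname(accession), description = unname(description),
    sequence = unname(seqs), category = cat_of(accession),
    has_x = grepl("X", seqs, fixed = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Write protein records to FASTA
#'
#' @param records A data frame with `accession`, `description`, `sequence`
#'   columns (e.g. from [read_fasta()] or a [merge_databases()] result).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  hdr <- ifelse(nzchar(records$description),
                paste(records$accession, records$description),
                records$accession)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read the RNA-source metadata sidecar
#'
#' OpenProt header layouts vary between releases, so RNA-source metadata is
#' supplied as an explicit four-column tab-separated sidecar with header
#' `accession`, `transcript_accession`, `biotype`, `orf_location` rather than
#' parsed from FASTA description lines.
#'
#' @param path Path to the TSV.
#' @return A data frame with the four columns; empty fields become `NA`.
#' @export
read_meta_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  needed <- c("accession", "transcript_accession", "biotype", "orf_location")
  missing <- setdiff(needed, names(meta))
  if (length(missing))
    stop("metadata TSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ok_bio <- c("protein_coding", "lncRNA", "pseudogene", "misc_RNA")
  ok_loc <- c("five_prime_utr", "cds_other_frame", "three_prime_utr",
              "novel_isoform", "ncRNA_orf")
  if (any(!is.na(meta$biotype) & !meta$biotype %in% ok_bio))
    stop("unknown biotype: ",
         meta$biotype[!is.na(meta$biotype) & !meta$biotype %in% ok_bio][1],
         call. = FALSE)
  if (any(!is.na(meta$orf_location) & !meta$orf_location %in% ok_loc))
    stop("unknown orf_location: ",
         meta$orf_location[!is.na(meta$orf_location) &
                           !meta$orf_location %in% ok_loc][1],
         call. = FALSE)
  meta[needed]
}
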