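#' Merge canonical, AltProt/Isoform and contaminant databases
#'
#' Combines the three record sets into one indexed search space, preserving
#' each record's category, and attaches RNA-source metadata by accession.
#' Accession sets must be pairwise disjoint.
#'
#' @param canonical,altprot,contaminants Record data frames from
#'   [read_fasta()]; `altprot` and `contaminants` may be `NULL` or empty.
#' @param meta Optional metadata data frame from [read_meta_tsv()].
#' @return An object of class `"protein_db"` (a data frame with columns
#'   `accession`, `description`, `sequence`, `category`, `has_x`,
#'   `transcript_accession`, `biotype`, `orf_location`).
#' @examples
#' cano <- data.frame(accession = c("P1", "P2"), description = "",
#'                    sequence = c("MKAAAR", "GGGK"),
#'                    category = "canonical", has_x = FALSE)
#' db <- merge_databases(cano, NULL, NULL)
#' nrow(db)
#' @export
merge_databases <- function(canonical, altprot = NULL, contaminants = NULL,
                            meta = NULL) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L,
                  list(canonical, altprot, contaminants))
  if (!length(parts)) stop("no records to merge", call. = FALSE)
  db <- do.call(rbind, parts)
  dup <- db$accession[duplicated(db$accession)]
  if (length(dup))
    stop("accession collision across databases: ", dup[1], call. = FALSE)
  db$transcript_accession <- NA_character_
  db$biotype <- NA_character_
  db$orf_location <- NA_character_
  if (!is.null(meta)) {
    idx <- match(db$accession, meta$accession)
    hit <- !is.na(idx)
    db$transcript_accession[hit] <- meta$transcript_accession[idx[hit]]
    db$biotype[hit] <- meta$biotype[idx[hit]]
    db$orf_location[hit] <- meta$orf_location[idx[hit]]
  }
  rownames(db) <- NULL
  class(db) <- c("protein_db", "data.frame")
  db
}

#' Look up records by accession
#'
#' @param db A `"protein_db"`.
#' @param accession Character vector of accessions.
#' @return The matching rows; unknown accessions are an error.
#' @export
db_lookup <- function(db, accession) {
  idx <- match(accession, db$accession)
  if (anyNA(idx))
    stop("accession not in database: ", accession[which(is.na(idx))[1]],
         call. = FALSE)
  db[idx, , drop = FALSE]
}

#' @export
print.protein_db <- function(x, ...) {
  cat("<protein_db> ", nrow(x), " records (",
      paste(sprintf("%s: %d", names(table(x$category)), table(x$category)),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Classify the RNA source of an AltProt or Isoform
#'
#' Maps a record's transcript biotype and ORF location onto the standard
#' RNA-source classes used to summarize alternative-protein origins:
#' `uORF` (5'UTR), `intORF` (out-of-frame within a CDS), `dORF` (3'UTR) for
#' ORFs on protein-coding mRNAs; `lncRNA` for ORFs on long non-coding RNAs
#' (pseudogene-derived transcripts are folded into this class, their raw
#' biotype staying on the record); `misc_RNA`; and `novel_isoform` for all
#' `II_` isoform records.
#'
#' @param record A single database row (one-row data frame or list) with
#'   `category`, `biotype` and `orf_location` fields.
#' @return One of `"uORF"`, `"intORF"`, `"dORF"`, `"lncRNA"`, `"misc_RNA"`,
#'   `"novel_isoform"`.
#' @export
classify_rna_source <- function(record) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L)
      stop("expected a single record", call. = FALSE)
    record <- as.list(record)
  }
  out <- .rna_source_vec(record$category, record$biotype, record$orf_location)
  if (is.na(out))
    stop("unclassifiable record", if (!is.null(record$accession))
         paste0(" '", record$accession, "'"),
         ": missing or inconsistent RNA-source metadata", call. = FALSE)
  out
}

# vectorized classifier; NA where unclassifiable, error on wrong category
.rna_source_vec <- function(category, biotype, orf_location) {
  if (any(!category %in% c("altprot", "isoform")))
    stop("RNA-source classification applies to altprot/isoform records only",
         call. = FALSE)
  n <- length(category)
  out <- rep(NA_character_, n)
  out[category == "isoform"] <- "novel_isoform"
  alt <- category == "altprot"
  pc <- alt & !is.na(biotype) & biotype == "protein_coding"
  out[pc & !is.na(orf_location) & orf_location == "five_prime_utr"] <- "uORF"
  out[pc & !is.na(orf_location) & orf_location == "cds_other_frame"] <- "intORF"
  out[pc & !is.na(orf_location) & orf_location == "three_prime_utr"] <- "dORF"
  out[alt & !is.na(biotype) & biotype %in% c("lncRNA", "pseudogene")] <- "lncRNA"
  out[alt & !is.na(biotype) & biotype == "misc_RNA"] <- "misc_RNA"
  out
}
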