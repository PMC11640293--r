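make_fasta <- function(...) {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(...), path)
  path
}

test_that("read_fasta parses headers, sequences and OpenProt categories", {
  f <- make_fasta(">IP_653613 predicted altprot", "MKR")
  rec <- read_fasta(f, "openprot")
  expect_equal(rec$accession, "IP_653613")
  expect_equal(rec$description, "predicted altprot")
  expect_equal(rec$sequence, "MKR")
  expect_equal(rec$category, "altprot")

  f2 <- make_fasta(">P1", "AAAA", ">P2", "GGGG")
  rec2 <- read_fasta(f2, "canonical")
  expect_equal(nrow(rec2), 2L)
  expect_equal(rec2$category, rep("canonical", 2))
  expect_equal(rec2$description, c("", ""))

  # wrapped sequence lines and lowercase input are normalized
  f3 <- make_fasta(">II_000001 iso", "mkaa", "GGLL")
  rec3 <- read_fasta(f3, "openprot")
  expect_equal(rec3$sequence, "MKAAGGLL")
  expect_equal(rec3$category, "isoform")
})

test_that("read_fasta rejects duplicates, bad residues and empty files", {
  f <- make_fasta(">P1", "AAAA", ">P1", "CCCC")
  expect_error(read_fasta(f, "canonical"), "duplicate accession.*P1")

  f2 <- make_fasta(">P1", "AA1A")
  expect_error(read_fasta(f2, "canonical"), "position 3")

  f3 <- tempfile(); file.create(f3)
  expect_error(read_fasta(f3, "canonical"), "empty")

  # X is allowed but flagged
  f4 <- make_fasta(">P1", "AAXA")
  expect_true(read_fasta(f4, "canonical")$has_x)

  # category/prefix consistency is enforced both ways
  f5 <- make_fasta(">IP_000001", "AAA")
  expect_error(read_fasta(f5, "canonical"), "prefix")
  f6 <- make_fasta(">P1", "AAA")
  expect_error(read_fasta(f6, "openprot"), "IP_/II_")
})

test_that("FASTA write/read round trip preserves every record", {
  set.seed(11)
  rec <- data.frame(
    accession = sprintf("P%03d", 1:20),
    description = c(sprintf("protein number %d", 1:10), rep("", 10)),
    sequence = vapply(1:20, function(i) random_sequence(sample(5:200, 1)), ""),
    stringsAsFactors = FALSE
  )
  f <- tempfile(fileext = ".fasta")
  write_fasta(rec, f)
  back <- read_fasta(f, "canonical")
  expect_equal(back$accession, rec$accession)
  expect_equal(back$description, rec$description)
  expect_equal(back$sequence, rec$sequence)
})

test_that("merge_databases preserves counts and rejects collisions", {
  cano <- data.frame(accession = c("P1", "P2"), description = "",
                     sequence = c("MKAAAR", "GGGK"), category = "canonical",
                     has_x = FALSE, stringsAsFactors = FALSE)
  alt <- data.frame(accession = "IP_000001", description = "",
                    sequence = "MPPK", category = "altprot", has_x = FALSE,
                    stringsAsFactors = FALSE)
  cont <- data.frame(accession = "CONT001", description = "",
                     sequence = "LLLK", category = "contaminant",
                     has_x = FALSE, stringsAsFactors = FALSE)
  db <- merge_databases(cano, alt, cont)
  expect_s3_class(db, "protein_db")
  expect_equal(nrow(db), 4L)
  expect_equal(sort(unique(db$category)),
               c("altprot", "canonical", "contaminant"))

  # empty altprot list is fine
  expect_equal(nrow(merge_databases(cano, NULL, cont)), 3L)

  # collision across inputs
  cont2 <- cont; cont2$accession <- "P1"
  expect_error(merge_databases(cano, alt, cont2), "collision.*P1")

  # merge order does not change what an accession resolves to
  db_a <- merge_databases(cano, alt, cont)
  db_b <- merge_databases(cano, NULL, cont)
  db_b <- merge_databases(db_b[FALSE, 1:5], alt, db_b[, 1:5])
  expect_equal(db_lookup(db_a, "IP_000001")$sequence,
               db_lookup(db_b, "IP_000001")$sequence)
  expect_error(db_lookup(db_a, "NOPE"), "not in database")
})

test_that("RNA-source classification follows biotype and ORF location", {
  row <- function(cat, bio = NA, loc = NA, acc = "IP_000001")
    list(accession = acc, category = cat, biotype = bio, orf_location = loc)

  expect_equal(classify_rna_source(row("isoform", acc = "II_629105")),
               "novel_isoform")
  expect_equal(classify_rna_source(row("altprot", "lncRNA", "ncRNA_orf")),
               "lncRNA")
  # pseudogene-derived transcripts fold into the lncRNA class
  expect_equal(classify_rna_source(row("altprot", "pseudogene", "ncRNA_orf")),
               "lncRNA")
  expect_equal(classify_rna_source(row("altprot", "misc_RNA", "ncRNA_orf")),
               "misc_RNA")
  expect_equal(
    classify_rna_source(row("altprot", "protein_coding", "five_prime_utr")),
    "uORF")
  expect_equal(
    classify_rna_source(row("altprot", "protein_coding", "cds_other_frame")),
    "intORF")
  expect_equal(
    classify_rna_source(row("altprot", "protein_coding", "three_prime_utr")),
    "dORF")

  expect_error(classify_rna_source(row("canonical")), "altprot/isoform")
  expect_error(classify_rna_source(row("altprot")), "unclassifiable")
  expect_error(classify_rna_source(row("altprot", "protein_coding", NA)),
               "unclassifiable")
})

test_that("metadata sidecar is validated on read", {
  f <- tempfile()
  writeLines(c("accession\ttranscript_accession\tbiotype\torf_location",
               "IP_1\tENST1\tlncRNA\tncRNA_orf"), f)
  meta <- read_meta_tsv(f)
  expect_equal(meta$biotype, "lncRNA")

  writeLines(c("accession\tbiotype", "IP_1\tlncRNA"), f)
  expect_error(read_meta_tsv(f), "missing column")

  writeLines(c("accession\ttranscript_accession\tbiotype\torf_location",
               "IP_1\tENST1\tnonsense\tncRNA_orf"), f)
  expect_error(read_meta_tsv(f), "unknown biotype")
})
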