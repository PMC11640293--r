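spectrum_from_peaks <- function(mz, intensity = NULL, id = "s1", charge = 2L) {
  if (is.null(intensity)) intensity <- rep(100, length(mz))
  o <- order(mz)
  list(spectrum_id = id, precursor_mz = 500, precursor_charge = charge,
       rt = NA_real_, peaks = data.frame(mz = mz[o], intensity = intensity[o]))
}

test_that("MGF read handles blocks, sorting, defaults and errors", {
  f <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=scan_1", "PEPMASS=500.25", "CHARGE=2+",
               "300.1 10", "100.2 5", "200.3 7", "END IONS"), f)
  sp <- read_mgf(f)
  expect_length(sp, 1L)
  expect_equal(sp[[1]]$spectrum_id, "scan_1")
  expect_equal(sp[[1]]$precursor_mz, 500.25)
  expect_equal(sp[[1]]$precursor_charge, 2L)
  expect_equal(nrow(sp[[1]]$peaks), 3L)
  # unsorted input comes back sorted with the same multiset of peaks
  expect_equal(sp[[1]]$peaks$mz, c(100.2, 200.3, 300.1))
  expect_equal(sp[[1]]$peaks$intensity, c(5, 7, 10))

  writeLines(c("BEGIN IONS", "TITLE=t", "CHARGE=2+", "100 1", "END IONS"), f)
  expect_error(read_mgf(f), "PEPMASS")

  writeLines(c("BEGIN IONS", "TITLE=t", "PEPMASS=400", "100 1", "END IONS"), f)
  expect_warning(sp2 <- read_mgf(f), "defaulting to 2\\+")
  expect_equal(sp2[[1]]$precursor_charge, 2L)

  writeLines(c("BEGIN IONS", "PEPMASS=400", "CHARGE=2+", "100 abc",
               "END IONS"), f)
  expect_error(read_mgf(f), "line 4")
})

test_that("MGF write/read round trips fixture spectra", {
  sp <- make_spectra(c("SAMPLEK", "PEPTIDER"), c(1, 0.5), seed = 5)
  f <- tempfile(fileext = ".mgf")
  write_mgf(sp$spectra, f)
  back <- read_mgf(f)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$spectrum_id, sp$spectra[[i]]$spectrum_id)
    expect_equal(back[[i]]$precursor_mz, sp$spectra[[i]]$precursor_mz,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$peaks$mz, sp$spectra[[i]]$peaks$mz,
                 tolerance = 1e-6)
  }
})

test_that("coverage counts distinct backbone sites", {
  # complete b ladder -> 1.0
  expect_equal(coverage_fraction(data.frame(series = "b", index = 1:7), 8), 1)
  # complementary b_i / y_{n-i} evidence the same site only once
  expect_equal(coverage_fraction(
    data.frame(series = c("b", "y"), index = c(3, 5)), 8), 1 / 7)
  # n=8, b1..b3 + y1..y3 -> sites {1,2,3,5,6,7}
  expect_equal(coverage_fraction(
    data.frame(series = rep(c("b", "y"), each = 3), index = c(1:3, 1:3)), 8),
    6 / 7)
  # n=10, b1..4 + y1..2 -> sites {1,2,3,4} u {8,9}
  expect_equal(coverage_fraction(
    data.frame(series = rep(c("b", "y"), c(4, 2)), index = c(1:4, 1:2)), 10),
    6 / 9)
  expect_equal(coverage_fraction(NULL, 10), 0)
  expect_error(coverage_fraction(data.frame(series = "b", index = 1), 1),
               ">= 2")
})

test_that("fragment matching recovers planted ladders deterministically", {
  pep <- "SAMPLEK"
  n <- nchar(pep)
  full_b <- fragment_mz(pep, "b", 1:(n - 1))
  psm <- match_fragments(spectrum_from_peaks(full_b), pep, charges = 1)
  expect_equal(psm$coverage, 1)

  none <- match_fragments(spectrum_from_peaks(c(100, 200, 300)), pep)
  expect_equal(none$coverage, 0)

  empty <- match_fragments(spectrum_from_peaks(numeric()), pep)
  expect_equal(empty$coverage, 0)
  expect_equal(empty$n_matched, 0L)

  # permuting peak order changes nothing
  set.seed(3)
  mz <- c(full_b[1:3], runif(5, 150, 900))
  a <- match_fragments(spectrum_from_peaks(mz), pep)
  b <- match_fragments(spectrum_from_peaks(rev(mz)), pep)
  expect_equal(a$matched_ions$mz_obs, b$matched_ions$mz_obs)
  expect_equal(a$coverage, b$coverage)

  # adding peaks never decreases coverage
  richer <- match_fragments(spectrum_from_peaks(c(mz, full_b[4])), pep)
  expect_gte(richer$coverage, a$coverage)
  expect_true(a$coverage >= 0 && a$coverage <= 1)
})

test_that("ties within tolerance resolve to the lower-m/z peak", {
  pep <- "SAMPLEK"
  b2 <- fragment_mz(pep, "b", 2)
  eps <- 2^-13                           # ~0.77 ppm, exactly representable
  psm <- match_fragments(spectrum_from_peaks(c(b2 - eps, b2 + eps)), pep,
                         tol_ppm = 20, charges = 1)
  hit <- psm$matched_ions[psm$matched_ions$series == "b" &
                          psm$matched_ions$index == 2, ]
  expect_equal(hit$mz_obs, b2 - eps)
})

test_that("the >= 75% coverage filter is inclusive and partitions the input", {
  mk <- function(cov) structure(list(coverage = cov), class = "annotated_psm")
  psms <- lapply(c(0.75, 0.7499, 0.9, 0.2, 1.0), mk)
  out <- apply_coverage_filter(psms)
  expect_length(out$kept, 3L)
  expect_length(out$rejected, 2L)
  expect_equal(vapply(out$kept, `[[`, 1, "coverage"), c(0.75, 0.9, 1.0))
  expect_length(c(out$kept, out$rejected), length(psms))

  # a stricter threshold keeps a subset
  strict <- apply_coverage_filter(psms, 0.9)
  expect_true(all(vapply(strict$kept, `[[`, 1, "coverage") %in%
                  vapply(out$kept, `[[`, 1, "coverage")))

  empty <- apply_coverage_filter(list())
  expect_length(empty$kept, 0L)
  expect_length(empty$rejected, 0L)
  expect_error(apply_coverage_filter(psms, 0), "threshold")
})

test_that("proteotypicity flags shared peptides and respects I/L collapse", {
  db <- merge_databases(
    data.frame(accession = c("P1", "P2"), description = "",
               sequence = c("AAASIKAAA", "CCCSLKCCC"), category = "canonical",
               has_x = FALSE, stringsAsFactors = FALSE),
    data.frame(accession = "IP_000001", description = "",
               sequence = "MMMSIKMMM", category = "altprot", has_x = FALSE,
               stringsAsFactors = FALSE))

  # SIK occurs in P1 and (under I/L collapse) in P2 and the AltProt
  res <- check_proteotypicity("SIK", db, target = "IP_000001")
  expect_false(res$proteotypic)
  expect_setequal(res$hits, c("P1", "P2", "IP_000001"))

  # without collapse, SLK no longer matches SIK
  res2 <- check_proteotypicity("SIK", db, target = "IP_000001",
                               il_equivalent = FALSE)
  expect_setequal(res2$hits, c("P1", "IP_000001"))

  uniq <- check_proteotypicity("MMMSIK", db, target = "IP_000001")
  expect_true(uniq$proteotypic)

  expect_error(check_proteotypicity("WWWWW", db, target = "IP_000001"),
               "inconsistent PSM")
})

test_that("proteotypicity agrees with the brute-force substring oracle", {
  set.seed(21)
  for (rep in 1:10) {
    db <- merge_databases(data.frame(
      accession = sprintf("P%03d", 1:30), description = "",
      sequence = vapply(1:30, function(i) random_sequence(sample(30:120, 1)), ""),
      category = "canonical", has_x = FALSE, stringsAsFactors = FALSE))
    # probe with substrings actually present and with random decoys
    probes <- c(substr(db$sequence[sample(30, 2)], 3, 10),
                random_sequence(8), random_sequence(6))
    for (pp in probes) for (il in c(TRUE, FALSE)) {
      got <- check_proteotypicity(pp, db, il_equivalent = il)
      expect_setequal(got$hits, oracle_hits(pp, db, il_equivalent = il))
      expect_equal(got$proteotypic, length(got$hits) == 1L)
    }
  }
})
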