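# Synthetic, fully ground-truthed inputs for every stage of the workflow.
# A single integer seed drives all randomness; each generator section seeds
# its own substream (seed + fixed offset) so adding one output never
# perturbs the others.

.random_sequences <- function(n, lengths) {
  vapply(seq_len(n), function(i)
    paste(sample(names(AA_FREQ), lengths[i], replace = TRUE,
                 prob = AA_FREQ), collapse = ""), "")
}

#' Generate a synthetic proteome with planted AltProts
#'
#' Emulates the three-part search space of the workflow: a canonical
#' proteome, an OpenProt-style AltProt/Isoform database (`IP_`/`II_`
#' accessions with transcript-biotype metadata) and common contaminants.
#' AltProt lengths are drawn uniformly from `altprot_length_range` (the
#' default 20--148 aa centres the length distribution near the ~84 aa median
#' typical of identified AltProts). A stated fraction of AltProts carries a
#' tryptic peptide copied verbatim from a canonical protein — planted
#' non-proteotypic cases listed in the ground-truth table. RNA-source
#' metadata is sampled lncRNA-heavy, echoing the observation that most
#' detected AltProts arise from transcripts annotated as non-coding.
#'
#' @param seed Integer seed; fixed seed implies identical output.
#' @param n_canonical,n_altprot,n_isoform,n_contaminant Record counts.
#' @param altprot_length_range Inclusive AltProt length range (aa).
#' @param shared_peptide_fraction Fraction of AltProts receiving a planted
#'   shared (non-proteotypic) peptide; requires `n_canonical > 0` when
#'   positive.
#' @param out_dir If non-`NULL`, writes `canonical.fasta`,
#'   `openprot.fasta`, `contaminants.fasta`, `meta.tsv` and
#'   `shared_peptides.tsv` there.
#' @return A list with `canonical`, `openprot`, `contaminants` (record data
#'   frames), `meta`, `shared_peptides` (ground truth: `altprot_accession`,
#'   `canonical_accession`, `peptide`) and `db`, the merged
#'   `"protein_db"`.
#' @export
make_proteome <- function(seed = 1L, n_canonical = 25L, n_altprot = 12L,
                          n_isoform = 3L, n_contaminant = 3L,
                          altprot_length_range = c(20L, 148L),
                          shared_peptide_fraction = 0.25,
                          out_dir = NULL) {
  if (shared_peptide_fraction < 0 || shared_peptide_fraction > 1)
    stop("shared_peptide_fraction must be in [0, 1]", call. = FALSE)
  n_shared <- round(shared_peptide_fraction * n_altprot)
  if (n_shared > 0L && n_canonical == 0L)
    stop("cannot plant shared peptides without canonical proteins",
         call. = FALSE)

  set.seed(seed)
  cano_seq <- .random_sequences(n_canonical,
                                sample(150:600, n_canonical, replace = TRUE))
  canonical <- data.frame(
    accession = sprintf("P%05d", seq_len(n_canonical)),
    description = sprintf("synthetic canonical protein %d",
                          seq_len(n_canonical)),
    sequence = cano_seq, category = "canonical",
    has_x = FALSE, stringsAsFactors = FALSE
  )

  set.seed(seed + 1L)
  alt_len <- sample(altprot_length_range[1]:altprot_length_range[2],
                    n_altprot, replace = TRUE)
  alt_seq <- .random_sequences(n_altprot, alt_len)
  shared <- NULL
  if (n_shared > 0L) {
    carriers <- sample(n_altprot, n_shared)
    donors <- sample(n_canonical, n_shared, replace = TRUE)
    rows <- vector("list", n_shared)
    for (i in seq_len(n_shared)) {
      peps <- digest(canonical$sequence[donors[i]],
                     length_range = c(7, 25))$sequence
      if (!length(peps))
        stop("donor protein yields no peptide of the required length",
             call. = FALSE)
      pep <- sample(peps, 1)
      host <- alt_seq[carriers[i]]
      plen <- nchar(pep)
      if (nchar(host) < plen + 4L)
        host <- paste0(host, .random_sequences(1, plen + 4L))
      p <- sample(3:(nchar(host) - plen), 1)
      # preceding R makes the insert a genuine tryptic peptide of the host
      substr(host, p - 1L, p - 1L) <- "R"
      substr(host, p, p + plen - 1L) <- pep
      alt_seq[carriers[i]] <- host
      rows[[i]] <- data.frame(
        altprot_accession = sprintf("IP_%06d", 600000L + carriers[i]),
        canonical_accession = canonical$accession[donors[i]],
        peptide = pep, stringsAsFactors = FALSE
      )
    }
    shared <- do.call(rbind, rows)
  }
  iso_seq <- .random_sequences(n_isoform,
                               sample(80:400, n_isoform, replace = TRUE))
  openprot <- data.frame(
    accession = c(sprintf("IP_%06d", 600000L + seq_len(n_altprot)),
                  sprintf("II_%06d", 600000L + seq_len(n_isoform))),
    description = c(sprintf("synthetic alternative protein %d",
                            seq_len(n_altprot)),
                    sprintf("synthetic novel isoform %d", seq_len(n_isoform))),
    sequence = c(alt_seq, iso_seq),
    category = rep(c("altprot", "isoform"), c(n_altprot, n_isoform)),
    has_x = FALSE, stringsAsFactors = FALSE
  )

  set.seed(seed + 2L)
  cont_seq <- .random_sequences(n_contaminant,
                                sample(100:400, n_contaminant, replace = TRUE))
  contaminants <- data.frame(
    accession = sprintf("CONT%03d", seq_len(n_contaminant)),
    description = sprintf("synthetic contaminant %d", seq_len(n_contaminant)),
    sequence = cont_seq, category = "contaminant",
    has_x = FALSE, stringsAsFactors = FALSE
  )

  set.seed(seed + 3L)
  # lncRNA-heavy source mix: ~70% predicted non-coding (incl. pseudogenes)
  src <- sample(c("lncRNA", "pseudogene", "misc_RNA",
                  "uORF", "intORF", "dORF"),
                n_altprot, replace = TRUE,
                prob = c(0.50, 0.20, 0.10, 0.08, 0.06, 0.06))
  biotype <- c(lncRNA = "lncRNA", pseudogene = "pseudogene",
               misc_RNA = "misc_RNA", uORF = "protein_coding",
               intORF = "protein_coding", dORF = "protein_coding")[src]
  orf_loc <- c(lncRNA = "ncRNA_orf", pseudogene = "ncRNA_orf",
               misc_RNA = "ncRNA_orf", uORF = "five_prime_utr",
               intORF = "cds_other_frame", dORF = "three_prime_utr")[src]
  meta <- data.frame(
    accession = openprot$accession,
    transcript_accession = sprintf("ENST%011d",
                                   sample.int(1e8, nrow(openprot))),
    biotype = c(unname(biotype), rep("protein_coding", n_isoform)),
    orf_location = c(unname(orf_loc), rep("novel_isoform", n_isoform)),
    stringsAsFactors = FALSE
  )

  db <- merge_databases(canonical, openprot, contaminants, meta)
  out <- list(canonical = canonical, openprot = openprot,
              contaminants = contaminants, meta = meta,
              shared_peptides = shared, db = db)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(canonical, file.path(out_dir, "canonical.fasta"))
    write_fasta(openprot, file.path(out_dir, "openprot.fasta"))
    write_fasta(contaminants, file.path(out_dir, "contaminants.fasta"))
    write.table(meta, file.path(out_dir, "meta.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(shared))
      write.table(shared, file.path(out_dir, "shared_peptides.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate synthetic spectra with controlled fragment coverage
#'
#' For each peptide, peaks are planted at the exact theoretical m/z of b/y
#' ions evidencing a chosen subset of backbone sites so that the recovered
#' coverage is exact, not probabilistic: the site subset is re-drawn until
#' no planted peak falls within tolerance of an ion of any other site, and
#' noise peaks are constrained at least `2 * tol_ppm` away from every
#' theoretical ion. Target coverages that are not representable as
#' `k / (n - 1)` are rounded to the nearest achievable value, which is
#' recorded in the ground truth.
#'
#' @param peptides Character vector of peptides (inline-tag notation
#'   allowed).
#' @param target_coverage Numeric vector in `[0, 1]`, recycled over
#'   peptides.
#' @param accessions Optional character vector of parent accessions per
#'   peptide (for the PSM table), recycled.
#' @param seed Integer seed.
#' @param tol_ppm Matching tolerance the spectra are built for.
#' @param charges Fragment charges the curation step will consider.
#' @param noise_peaks Number of decoy peaks per spectrum.
#' @param precursor_charge Precursor charge of every PSM.
#' @param mz_range m/z range for noise peaks.
#' @param out_dir If non-`NULL`, writes `spectra.mgf`, `psms.tsv` and
#'   `coverage_truth.tsv` there.
#' @return A list with `spectra` (list, [read_mgf()] layout), `psms` (data
#'   frame: `spectrum_id`, `peptide`, `charge`, `accessions`), `truth`
#'   (`spectrum_id`, `peptide`, `target_coverage`, `achieved_coverage`) and
#'   `rt`, a named retention-time vector (minutes).
#' @export
make_spectra <- function(peptides, target_coverage, accessions = NULL,
                         seed = 1L, tol_ppm = 20, charges = c(1L, 2L),
                         noise_peaks = 10L, precursor_charge = 2L,
                         mz_range = c(150, 1500), out_dir = NULL) {
  np <- length(peptides)
  target_coverage <- rep_len(target_coverage, np)
  if (is.null(accessions)) accessions <- "SYNTH"
  accessions <- rep_len(accessions, np)
  spectra <- vector("list", np)
  achieved <- numeric(np)
  rt <- numeric(np)
  for (i in seq_len(np)) {
    set.seed(seed + 10L * i)
    pep <- parse_peptide(peptides[i])
    n <- nchar(pep$sequence)
    nm1 <- n - 1L
    theo <- enumerate_fragments(pep, charges)
    theo_site <- ifelse(theo$series == "b", theo$index, n - theo$index)
    k <- round(target_coverage[i] * nm1)
    planted <- NULL
    got <- integer()
    for (try in seq_len(30L)) {
      sites <- if (k > 0L) sort(sample.int(nm1, k)) else integer()
      series <- sample(c("b", "y"), length(sites), replace = TRUE)
      idx <- ifelse(series == "b", sites, n - sites)
      mz <- vapply(seq_along(sites), function(j)
        fragment_mz(pep, series[j], idx[j], 1L), numeric(1))
      # sites actually evidenced by these peaks under the matcher's rules
      got <- unique(theo_site[vapply(theo$mz, function(tm)
        any(abs(mz - tm) / tm * 1e6 <= tol_ppm), logical(1))])
      if (setequal(got, sites)) break
    }
    planted <- data.frame(mz = mz,
                          intensity = runif(length(mz), 1e3, 1e4))
    achieved[i] <- length(got) / nm1
    noise <- numeric(0)
    while (length(noise) < noise_peaks) {
      cand <- runif(noise_peaks, mz_range[1], mz_range[2])
      ok <- vapply(cand, function(m)
        all(abs(theo$mz - m) / theo$mz * 1e6 > 2 * tol_ppm), logical(1))
      noise <- c(noise, cand[ok])
    }
    noise <- noise[seq_len(noise_peaks)]
    peaks <- rbind(planted,
                   data.frame(mz = noise,
                              intensity = runif(noise_peaks, 10, 1e3)))
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    rt[i] <- runif(1, 5, 90)
    spectra[[i]] <- list(
      spectrum_id = sprintf("scan_%05d", i),
      precursor_mz = precursor_mz(pep, precursor_charge),
      precursor_charge = precursor_charge,
      rt = rt[i] * 60, peaks = peaks
    )
  }
  ids <- vapply(spectra, function(s) s$spectrum_id, "")
  names(rt) <- ids
  psms <- data.frame(spectrum_id = ids,
                     peptide = vapply(peptides, function(p)
                       peptide_notation(parse_peptide(p)), "",
                       USE.NAMES = FALSE),
                     charge = precursor_charge,
                     accessions = accessions, stringsAsFactors = FALSE)
  truth <- data.frame(spectrum_id = ids, peptide = psms$peptide,
                      target_coverage = target_coverage,
                      achieved_coverage = achieved,
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mgf(spectra, file.path(out_dir, "spectra.mgf"))
    write.table(psms, file.path(out_dir, "psms.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(out_dir, "coverage_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(spectra = spectra, psms = psms, truth = truth, rt = rt)
}

#' Generate a synthetic DIA quantification report with planted effects
#'
#' Log2 intensities are `baseline + delta * [group 1] + N(0, sigma)`;
#' planted per-protein effects `delta` and the missingness pattern are
#' returned as ground truth. `missing_mode = "random"` masks cells at
#' `missing_rate` uniformly; `"group_exclusive"` additionally blanks
#' `n_exclusive` proteins entirely in group 2, emulating presence/absence
#' cases. The defaults mirror the study layout: two groups of cell-line
#' replicates, 4 vs 4 runs, sigma = 0.3 log2 units.
#'
#' @param seed Integer seed.
#' @param n_proteins Number of protein groups.
#' @param n_per_group Length-2 integer, runs per group.
#' @param effect_sizes,effect_props Planted log2 effects and their
#'   proportions (deterministic counts, shuffled).
#' @param sigma Gaussian noise sd in log2 units.
#' @param missing_rate Random missingness rate in `[0, 1]`.
#' @param missing_mode `"random"` or `"group_exclusive"`.
#' @param n_exclusive Number of group-exclusive proteins (mode
#'   `"group_exclusive"`).
#' @param baseline_range Uniform range of per-protein baseline log2
#'   intensity.
#' @param group_labels Length-2 character, group names (group 1 first).
#' @param out_file If non-`NULL`, writes the long-format TSV there.
#' @return A list with `report` (long data frame: `Run`, `Protein.Group`,
#'   `PG.MaxLFQ`), `groups` (named character vector run -> label), `truth`
#'   (`accession`, `delta`, `exclusive`) and `mat`, the complete pre-pivot
#'   matrix with `NA` for missing cells.
#' @export
make_dia_report <- function(seed = 1L, n_proteins = 500L,
                            n_per_group = c(4L, 4L),
                            effect_sizes = c(0, 1.5, -1.5),
                            effect_props = c(0.8, 0.1, 0.1),
                            sigma = 0.3, missing_rate = 0.1,
                            missing_mode = c("random", "group_exclusive"),
                            n_exclusive = 0L,
                            baseline_range = c(16, 24),
                            group_labels = c("pancreatic", "other"),
                            out_file = NULL) {
  missing_mode <- match.arg(missing_mode)
  if (any(n_per_group < 2L))
    warning("fewer than 2 runs in a group: most proteins will be untestable",
            call. = FALSE)
  set.seed(seed + 5L)
  counts <- round(effect_props / sum(effect_props) * n_proteins)
  counts[1] <- n_proteins - sum(counts[-1])
  delta <- sample(rep(effect_sizes, counts))
  acc <- sprintf("PG%05d", seq_len(n_proteins))
  runs <- c(paste0(group_labels[1], "_", seq_len(n_per_group[1])),
            paste0(group_labels[2], "_", seq_len(n_per_group[2])))
  groups <- setNames(rep(group_labels, n_per_group), runs)
  baseline <- runif(n_proteins, baseline_range[1], baseline_range[2])
  lg <- outer(baseline, rep(0, length(runs)), "+") +
    outer(delta, as.numeric(groups == group_labels[1])) +
    matrix(rnorm(n_proteins * length(runs), sd = sigma),
           n_proteins, length(runs))
  dimnames(lg) <- list(acc, runs)
  mat <- 2^lg
  if (missing_rate > 0)
    mat[matrix(runif(length(mat)) < missing_rate, nrow(mat))] <- NA
  exclusive <- rep(FALSE, n_proteins)
  if (missing_mode == "group_exclusive" && n_exclusive > 0L) {
    ex <- sample.int(n_proteins, n_exclusive)
    exclusive[ex] <- TRUE
    mat[ex, groups == group_labels[2]] <- NA
    # guarantee full presence on the retained side
    mat[ex, groups == group_labels[1]] <-
      2^(baseline[ex] + delta[ex] +
         matrix(rnorm(n_exclusive * n_per_group[1], sd = sigma),
                n_exclusive, n_per_group[1]))
  }
  obs <- which(!is.na(mat), arr.ind = TRUE)
  report <- data.frame(Run = colnames(mat)[obs[, 2]],
                       Protein.Group = rownames(mat)[obs[, 1]],
                       PG.MaxLFQ = mat[obs], stringsAsFactors = FALSE)
  report <- report[order(report$Run, report$Protein.Group), ]
  rownames(report) <- NULL
  if (!is.null(out_file))
    write.table(report, out_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(report = report,
       groups = groups,
       truth = data.frame(accession = acc, delta = delta,
                          exclusive = exclusive, stringsAsFactors = FALSE),
       mat = mat)
}
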