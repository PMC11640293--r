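---
title: "Curating and quantifying alternative proteins: methods and design"
author: "altprotcurator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and quantifying alternative proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altprotcurator)
```

## The problem

Alternative proteins (AltProts, also called microproteins or sORF-encoded
peptides) are translated from open reading frames missing from reference
annotations: ORFs on long non-coding RNAs or pseudogene transcripts, in the
5' or 3' UTR of mRNAs (uORFs and dORFs), or out-of-frame within an annotated
coding sequence (intORFs). They are short — median lengths near 84 amino
acids are typical of detected sets — so trypsin usually yields only one or
two observable peptides per protein. A single peptide-spectrum match (PSM)
therefore carries the whole identification, and the evidence standards have
to be raised accordingly: the fragment ions must cover most of the peptide
backbone, and the peptide must be proteotypic, i.e. occur in exactly one
protein of the search space.

This package implements the downstream, fully reproducible side of a
combined DDA/DIA discovery workflow for AltProts: database assembly, mass
arithmetic, PSM curation, spectral-library construction, DIA window design,
differential quantification, and property profiling. Upstream steps —
database search, rescoring, FDR control, and manual review by human
operators — are deliberately out of scope: the package consumes
already-searched PSM tables and DIA quantification reports.

## Database assembly

The search space is the union of three FASTA databases: a canonical
proteome, an OpenProt-style AltProt/Isoform database, and common
contaminants. OpenProt accession prefixes determine the class: `IP_` for
predicted alternative proteins, `II_` for novel isoforms; `read_fasta()`
enforces this convention, and `merge_databases()` requires pairwise-disjoint
accessions.

RNA-source metadata (transcript accession, biotype, ORF location) is
supplied as an explicit four-column TSV sidecar rather than parsed from
FASTA headers. OpenProt header layouts vary between releases, so an explicit
contract is more robust than header-dialect detection; the caller decides
how transcripts with ambiguous biotypes are assigned. `classify_rna_source()`
maps the metadata onto the standard summary classes (uORF, intORF, dORF,
lncRNA, misc_RNA, novel_isoform). Pseudogene-derived transcripts are folded
into the lncRNA class for summaries — they belong to the "predicted
non-coding" fraction — while the raw biotype stays on the record.

Sequences containing `X` (unknown residue) are accepted and flagged, but
excluded from digestion and all mass computations, whose results would be
undefined.

## Mass arithmetic

All masses are monoisotopic (Orbitrap-class data), with proton mass
1.007276 Da and water 18.010565 Da. Digestion follows classical trypsin:
cleavage after K or R, not before proline; the proline exception matches the
default trypsin rule of common search engines and can be disabled
(`proline_rule = FALSE`). Missed cleavages up to a configurable maximum are
enumerated combinatorially.

Modified peptides use an inline-tag grammar — `"AC[+57.02146]K"`, with an
N-terminal tag written `"[+42.01057]-MK..."` — that round-trips bit-exactly
at five decimal places. The three modifications of the standard search
configuration ship as defaults: carbamidomethyl-C (+57.02146, fixed),
oxidation-M (+15.99491, variable) and protein N-terminal acetylation
(+42.01057, variable). Acetylation is restricted to protein N-termini by
default, the conservative reading when a search configuration does not say
otherwise.

Fragment m/z follows the b/y conventions: a b ion of index *i* is the sum of
the first *i* residue (+modification) masses plus charge protons, divided by
charge; a y ion adds one water to the last *j* residues. N-terminal
modifications count toward b ions only. Fragment charges default to {1, 2}:
higher fragment charges are rarely informative for tryptic peptides at these
lengths. Only b and y series are modeled — the curation rule below is
defined on them — with no neutral losses or isotope envelopes.

## PSM curation by backbone coverage

The central curation rule keeps a PSM only if its matched y/b ions cover at
least 75% of the peptide sequence. "Coverage" needs a definition to be
computable; the one implemented is the fraction of the *n − 1* inter-residue
fragmentation sites of a length-*n* peptide evidenced by at least one
matched b or y ion (a b ion of index *i* evidences site *i*, a y ion of
index *j* evidences site *n − j*, and complementary pairs count their shared
site once). This definition makes 100% achievable and maps 1:1 onto the ion
indices. A residue-based alternative (fraction of residues spanned by
matched fragments) is available via `coverage_method = "residue"`. The b and
y ladders are pooled (union) when counting sites; a per-series variant would
be stricter and is not the default reading of "y or b ions".

Matching assigns each theoretical ion to the nearest peak within a ppm
tolerance, defaulting to 20 ppm (HCD Orbitrap MS2 at 15,000 resolution);
exact-distance ties go to the lower-m/z peak so results are deterministic
and independent of peak order. The 75% threshold is inclusive ("at least"),
and the filter partitions its input exhaustively.

The workflow's manual two-operator review cannot be automated and is
represented only as a `validated` flag importable from a reviewer TSV; the
software never sets it.

Proteotypicity is a substring scan of the whole merged database, with I/L
collapsed by default since leucine and isoleucine are isobaric. A peptide is
proteotypic when it occurs in exactly its one claimed parent; a peptide
absent from its claimed parent is an inconsistent PSM and an error.

## Spectral library and DIA windows

Curated PSMs become a spectral library with one entry per (modified peptide,
precursor charge); duplicates resolve by maximum coverage, then matched-ion
count, then lexicographic spectrum id. Fragment intensities are taken from
the matched peaks and renormalized to a maximum of 1 per precursor, and
precursors with fewer than 3 fragments (configurable floor) are dropped as
unusable for DIA scoring.

The on-disk format is the OpenSWATH-style TSV that DIA-NN documents as an
accepted library input, with a fixed 13-column header; this favors
interoperability over inventing a dialect. No external iRT standard is
assumed: retention times are rescaled linearly to 0–100 over the run span,
and the file carries a `#irt=linear0-100` meta line declaring that
convention.

`make_window_scheme()` builds staggered DIA isolation schemes: pass 1 tiles
the precursor range with contiguous windows; a non-zero offset adds a second
interleaved pass. The acquisition design used for this kind of experiment —
2 × 75 windows of 8 m/z staggered by 4 m/z over 400–1000 m/z — is
`make_window_scheme(400, 1000, 8, 4)`.

## Differential quantification

DIA quantification reports are pivoted into a protein-group × run matrix in
which an unreported (protein, run) pair stays `NA`. No operation in the
package ever imputes: missingness survives normalization and testing, and
presence/absence information is handled by an explicit exclusivity class
instead of zero-filling.

Normalization is median centering on the log2 scale (each run's median of
observed values is equalized, preserving the grand median). The upstream
tooling's normalization step is not specified beyond its name, and median
centering is the standard intensity normalization of that family of tools;
quantile normalization (via limma) sits behind `method = "quantile"` for
comparison.

Per protein, Welch's unequal-variance *t*-test is applied to the log2
intensities of observed values (at least two per group), with
Welch–Satterthwaite degrees of freedom and two-sided p-values. Fold changes
are the log2 ratio of linear-scale group means of observed values — stated
explicitly because means-of-logs and logs-of-means differ. Volcano classes
use the conventional gates: `up_in_group1` when p < 0.05 and log2 fold
change > 1 for AltProt-scale comparisons (0.01 for deep canonical
proteomes), with the symmetric rule on the negative side. A protein observed
in at least 3 runs of one group (cell lines typically have 3–4 replicates)
and none of the other is `exclusive` to that group. Raw p-values gate the
classes — mirroring the fold-change-plus-p-value practice of this kind of
analysis — and a Benjamini–Hochberg FDR column is emitted for information
only.

`dia_differential()` packages all of this as a classed result with
`print()`, `summary()`, `plot()` (volcano) and `as.data.frame()` methods.

## Isoelectric point and profiling

The pI is the root of the Henderson–Hasselbalch net-charge function over
nine ionizable groups (both termini plus D, E, C, Y, H, K, R), found by
bisection on pH ∈ [0, 14] to 1e-4 pH units. The function is strictly
decreasing and bracketed — the termini guarantee a positive charge at pH 0
and a negative one at pH 14 — so the root exists and is unique. Published
pKa sets disagree by up to ~0.5 pH units, so the set is pluggable
(`pka_sets`): EMBOSS values are the default, Bjellqvist's are included.
Reported pI medians are therefore comparable only within one pKa set.

`summarize_profiles()` reports length histograms (50-aa bins), pI histograms
(1-pH bins over [3, 13) with open outer bins), RNA-source proportions and
medians over the AltProt/Isoform records of a database.

## The synthetic fixture generator

All tests run on synthetic, fully ground-truthed fixtures; no instrument
data is required.

* `make_proteome()` emulates the three-part search space. Defaults: 25
  canonical proteins (150–600 aa), 12 AltProts drawn uniformly from
  20–148 aa (centering lengths near the ~84-aa median typical of detected
  AltProt sets), 3 isoforms, 3 contaminants. A configurable fraction of
  AltProts (default 25%) receives a tryptic peptide copied from a canonical
  protein — planted non-proteotypic cases recorded in a ground-truth table.
  RNA-source metadata is sampled lncRNA-heavy (50% lncRNA, 20% pseudogene,
  10% misc_RNA, 20% mRNA ORFs), echoing the observation that most detected
  AltProts map to transcripts annotated as non-coding.
* `make_spectra()` plants peaks at exact theoretical b/y m/z for a chosen
  subset of backbone sites, so ground-truth coverage is exact rather than
  probabilistic: site subsets are re-drawn if a planted peak would
  accidentally evidence another site within tolerance, and noise peaks are
  kept at least twice the tolerance away from every theoretical ion.
  Coverage targets not representable as k/(n − 1) round to the nearest
  achievable value, which is what the ground truth records.
* `make_dia_report()` plants per-protein log2 effects (default 80% null,
  10% at +1.5, 10% at −1.5) on 4 + 4 runs with Gaussian noise of 0.3 log2
  units and 10% random missingness — the replicate structure and effect
  scale of a two-group cell-line comparison — or blanks chosen proteins in
  one group entirely to emulate presence/absence cases.

A single integer seed drives everything; each generator section derives its
own substream from fixed offsets, so regenerating one output never perturbs
another.

What the fixtures do *not* model is as important as what they do: no
fragmentation-intensity profiles, chromatographic peak shapes, interference,
or FAIMS behavior. Passing tests demonstrate the correctness of the
arithmetic, the filters and the statistics — not the end-to-end performance
of the workflow on instrument data, which additionally depends on the
upstream search and scoring stack.

## Numerical choices and degenerate inputs

* Residue masses carry five decimals; mass agreement with an independent
  elemental-composition oracle is maintained to 1e-4 Da, and the b/y
  complementarity identity to 1e-9 Da.
* Fragment matching ties break toward the lower-m/z peak; library
  deduplication ties break by matched-ion count then spectrum id — both
  fully deterministic.
* An empty peak list yields coverage 0, not an error; a peptide of length
  < 2 has no backbone sites and is an error.
* Zero-variance group pairs and groups with fewer than two observations are
  `untestable`, never silently assigned p-values.
* Runs with no observed values cannot be normalized and are an error, as
  are non-positive intensities on the log scale.

## Problem sizes used in the test suite

The shipped tests exercise: 1,000 random digests for the concatenation
property; 100-peptide mass-oracle sweeps; 200 planted PSMs spanning the
0.74/0.75/0.76 filter boundary (built on length-101 peptides so those
coverages are exactly representable as k/100); 50 random databases for the
proteotypicity oracle; a 500-protein, 4 + 4-run DIA simulation at the
planted-effect conditions above; 1,000 Welch comparisons against the
closed-form oracle; a 1,000-precursor library round trip; and 10,000 random
sequences for the pI defining property. These sizes make the full suite run
in well under a minute while keeping every boundary case exercised.

## Known limitations

* No database search, rescoring or FDR estimation; PSMs arrive
  pre-validated.
* Only b/y singly/doubly charged fragments; no neutral losses.
* The library writer emits one dialect; it does not convert third-party
  library formats.
* Exact reproduction of published pI ranges requires the original tool's
  pKa set, which is rarely reported; the pluggable sets bound the
  disagreement but cannot remove it.
* `X`-containing sequences are tracked but invisible to mass and pI
  computations.
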