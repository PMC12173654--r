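---
title: "Screening long-range PCR amplicons for slipped-strand deletion artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening long-range PCR amplicons for slipped-strand deletion artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slipscan)
```

## The problem

Large genes riddled with repeats — the canonical example being *VWF*,
~178 kb with 14 Alu repeats, a polymorphic TCTA simple repeat, and a
pseudogene 97% identical to a 12-exon stretch — resist both short-read
sequencing and routine Sanger walking. A practical alternative is to
tile the locus with overlapping 12–15 kb long-range PCR products and
sequence the pooled amplicons on a nanopore instrument. The trade-off
is that long-range polymerases traversing repetitive templates can
slip: when two similar sequence copies ("direct repeats") flank a
spacer, the nascent strand can detach at the first copy and re-anneal
at the second, excising the spacer plus one copy and yielding a
*deletion-bearing amplicon from a non-deleted genome*. Downstream,
such molecules look exactly like a genuine heterozygous structural
deletion: a second, shorter read population and a clean split-read
signal.

slipscan automates the read-level screen that distinguishes the two
cases. The core idea is allele counting. A diploid locus has two
haplotypes, tagged along the amplicon by heterozygous SNVs. If the
deletion is real, full-length reads all come from one haplotype and
deletion-form reads from the other — two allele classes, and no
heterozygous SNVs can exist *inside* a truly deleted span. If the
deletion is a PCR artifact, the deletion-form reads carry the same SNV
fingerprint as one of the two full-length read groups — three allele
classes in total — and called heterozygous SNVs typically persist
inside the putatively deleted interval because the full-length reads
covering it come from both haplotypes.

## Workflow and model

The screen runs in seven steps, each exposed as an ordinary function
and chained by `run_artifact_check()`:

1. **Gating** (`filter_reads`). Reads are kept when the mean read
   quality strictly exceeds 9 and the length lies in
   [8,000, 16,000] nt. Mean quality is computed as
   $-10\log_{10}(\overline{p_{err}})$ over per-base error
   probabilities, the convention of long-read filtering tools, so a
   read is penalised by its worst bases.
2. **Amplicon assignment** (`assign_amplicon`). Each tiling amplicon
   carries a 20-nt anchor that occurs near one end of its product but
   may occur mid-read in an overlapping product. A read is assigned
   when the anchor (or its reverse complement) occurs with at most 2
   Hamming mismatches within a per-amplicon end window, 2,000 bp by
   default. The window quantifies "near the end": it must accept an
   anchor a few hundred bases from the product end while rejecting the
   same sequence ~5,900 bp from both ends of an overlapping product's
   reads. Matching is substitution-only; an indel inside the 20-mer
   defeats it, which is why the bundled fixtures model post-gate
   substitution noise (see below).
3. **Form binning** (`classify_length`). Reads are binned to
   structural forms (full-length vs deletion) by length windows of
   ±300 bp. Observed per-form spreads in this kind of data are an
   order of magnitude tighter (tens of bp), so 300 bp gives indel
   headroom while keeping forms separated by a multi-kb deletion
   unambiguous; the constructor rejects overlapping windows.
4. **Alignment** (`align_to_forms`). Each read is aligned to the
   candidate forms by a banded global alignment under unit edit costs
   (implemented in C++), keeping the form with the lowest normalized
   edit distance. Within the band the alignment is optimal; forms are
   skipped only by the exact dominance bound
   $d \ge |n - m|$, never heuristically. A read whose best
   normalized distance exceeds 0.25 is unalignable and dropped.
5. **Per-read genotyping** (`genotype_read`). At each phased het SNV
   the aligned read base is called `A`, `B`, `other` (sequencing
   error) or `absent` (inside the form's deleted span, or an alignment
   deletion). `assign_haplotype` then takes a majority vote,
   requiring ≥3 informative sites and tolerating a minority fraction
   up to 0.2 — explicit, configurable thresholds standing in for what
   is otherwise a manual visual inspection.
6. **Incongruence** (`detect_incongruence`). Allele classes are
   distinct (haplotype, form) pairs holding ≥5% of classified reads.
   The verdict is `artifact_suspected` when ≥90% of deletion-form
   reads share a haplotype with a full-length class (the 0.9, rather
   than "all", tolerates occasional chimeric or misassigned reads) or
   when ≥1 het SNV lies strictly inside the candidate deletion;
   `consistent` when reads split into exactly two haplotype-disjoint
   classes with no interior SNV; `indeterminate` otherwise — kept as a
   distinct outcome because a shared haplotype with only two observed
   classes could equally reflect missing data or genuine mosaicism.
   Breakpoint bases are excluded from "inside" because alignment
   placement at the breakpoints is ambiguous.
7. **Breakpoint scan** (`find_direct_repeats`,
   `apply_haplotype_and_rescan`, `slippage_propensity`). The deletion
   is first left-aligned (VCF normalization convention), then the
   flanks are searched exhaustively for the longest pair of
   same-strand copies, compared without indels at ≤10% mismatches,
   with each copy starting within 300 bp of its breakpoint and
   overlapping or abutting it. The scan is repeated after substituting
   the suspect haplotype's alleles, because het SNVs near a breakpoint
   can convert an interrupted, inert repeat into a long perfect one on
   a single allele. A haplotype-level repeat of ≥15 bp is flagged
   `elevated`: shorter repeats, like those in most reference
   sequences, have little effect on long-range PCR. The minimum
   reportable length (8), window (300 bp) and mismatch fraction (0.1)
   are design choices: the geometry that must be detectable is a
   ~250 bp SNV-modified repeat region adjoining a breakpoint, while
   random 50%-GC sequence must scan to length 0.

Inverted repeats are deliberately out of scope (the slippage geometry
is same-strand), as are thermodynamic hairpin predictions and
polymerase kinetics: the scanner reports sequence geometry and leaves
mechanism to the reader.

## The simulator: what it emulates and what it does not

`sim_locus()` builds a seeded diploid single-amplicon locus that
mirrors the canonical screening scenario numerically: an 11,941 bp
full-length product; a 2,599 bp candidate deletion (deleted form
9,342 bp); direct-repeat copies of 28 bp abutting the two breakpoints
exactly one deletion-length apart, so that deleting the interval
merges them seamlessly; a reference repeat interrupted at 8 positions
whose haplotype-B alleles restore the full 28 bp copy; 5 het SNVs
strictly inside the deletion; 12 flanking het SNVs; and the 20-nt
anchor 480 bp from the 3' end. Haplotype A equals the reference at
every site. All the interrupting SNVs lie left of the left breakpoint,
so the interior het count stays 5.

`simulate_pcr_pool()` models slippage as a per-molecule Bernoulli
event — 0.70 for the extended-repeat haplotype, 0.05 for the reference
haplotype — matching end-point amplicon proportions without per-cycle
branching. `simulate_reads()` adds substitution and indel noise,
random orientation, and constant per-base qualities consistent with
the substitution rate ($Q = -10\log_{10} p_{sub}$), which is all the
quality gate observes.

The canonical regression fixture (`patient_fixture()`, seed 42) draws
50 reads in the 13 hapA-normal / 11 hapB-normal / 26 hapB-deleted
composition with 1% substitution error and no indels. Substitution-only
noise is a deliberate choice, not an oversight: anchor matching is
Hamming-based by design, and the fixture models reads after quality
gating, where the question is whether the *logic* of the screen —
binning, genotyping, allele counting — recovers the planted truth.
Indel robustness is exercised separately (alignment tests, length
binning under 1% indels). What passing fixtures do **not** show:
tolerance to real pore-specific error profiles (homopolymer
compression, strand-biased errors), chimeric reads, sample
contamination, or more than two structural forms per amplicon. The
aligner and the pileup caller are simplified stand-ins kept behind
interfaces, so externally called variants (VCF) and externally
assigned reads can replace them.

## Numerical and degenerate-case choices

* Coordinates are 0-based half-open internally; HGVS strings (1-based
  inclusive) are converted only at I/O boundaries.
* Anchor ties across amplicons leave a read unassigned with an
  `ambiguous` flag rather than guessing; equal-mismatch hits in both
  orientations yield orientation `unknown`.
* The banded aligner prefers the diagonal on ties, keeping the
  reference-coordinate map dense; band width is the length difference
  plus max(150, 2% of form length). An off-band optimum can only make
  a read look worse than it is, i.e. errs toward `unalignable`.
* The repeat scanner's tie-break is longest, then fewest mismatches,
  then leftmost. A candidate of length $L$ may contain at most
  $\lfloor 0.1 L \rfloor$ mismatches at every prefix considered.
* The internal het caller requires depth ≥20 and a second-allele
  fraction in [0.2, 0.8]; discovered sites are phased against the
  deepest site by read co-occurrence. With ~50 informative reads the
  binomial error probability of a spurious 20% second allele at 1%
  substitution noise is negligible (<10⁻³ genome-wide).
* `detect_incongruence` errors out (rather than returning a verdict)
  when there are no deletion-form reads: there is no candidate to
  evaluate.
* Allele classes below 5 reads make the verdict `indeterminate`
  unless positive artifact evidence is present.

## Problem sizes used by the test suite

Tests that need many alignments use a scaled-down locus (3,000 bp,
700 bp deletion) so the whole suite runs in a few minutes: 500 reads
for the genotyping-accuracy check, 100 random instances for the
repeat-scanner oracle, 30 random pairs against the Levenshtein oracle.
The two end-to-end fixtures run at full 11,941 bp scale with 50 and 40
reads. The slippage calibration check uses 10,000 molecules per
haplotype, where three binomial standard deviations are ±1.4
percentage points around 0.70.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile("fixture")
fx <- patient_fixture(dir)                    # seed-42 canonical fixture
report <- run_artifact_check(
  fastq = fx$paths$fastq,
  forms_fasta = fx$paths$forms_fasta,
  candidate_del = "g.5001_7599del",           # local HGVS, 2,599 bp
  scheme = fx$paths$scheme,
  het_sites_file = fx$paths$het_sites)
report
```

The report prints the class table (13 + 11 full-length, 26 deleted on
the minor full-length haplotype), the `artifact_suspected` verdict
with 3 allele classes and 5 interior het SNVs, and the breakpoint
context in which the suspect haplotype's repeat is extended well past
the 15 bp propensity threshold while the reference repeat is not.

## Known limitations

* Phasing is within-amplicon only; stitching haplotypes across a
  tiling scheme is out of scope.
* The scheme validator checks interval arithmetic (sizes, gaps,
  adjacent overlaps, with fully-contained amplicons treated as
  deliberate bridges), not primer chemistry.
* Depth for the specificity QC is assignment-based (each read covers
  its amplicon's full interval); base-resolution depth requires an
  external aligner and can be supplied directly to
  `off_target_specificity()`.
* The consequence annotator handles single-base substitutions against
  a supplied CDS and the g./c. coordinate dialects used in deletion
  screening; it is not a general HGVS engine.
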