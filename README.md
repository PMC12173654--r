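# slipscan

Artifact screening for long-range PCR amplicon sequencing on long-read
(nanopore) platforms.

## Why

Tiling a large, repeat-laden gene (the motivating case is *VWF*,
~178 kb, Alu-dense, shadowed by a 97%-identical pseudogene) with
overlapping 12–15 kb long-range PCR products makes the whole locus
sequenceable on a nanopore flow cell — but long-range polymerases slip
on direct repeats. Two similar sequence copies flanking a spacer can
form a slipped-strand structure during amplification that excises the
spacer and one copy, producing deletion-bearing amplicons from a
genome that has no deletion. In the variant calls this is
indistinguishable from a real heterozygous structural deletion.

slipscan automates the read-level screen that separates the two cases
by **allele counting over per-read haplotypes**. Reads of one amplicon
are gated on quality/length, binned by length into structural forms
(full-length vs deletion), and genotyped at phased heterozygous SNVs;
each read gets a haplotype by majority vote. For a genuine
heterozygous deletion the reads partition into **two** allele classes
(full-length reads of one haplotype, deletion reads of the other) and
no het SNV can lie inside the deleted span. A slippage artifact shows
**three** classes — the deletion reads share a haplotype with one of
the full-length groups — and het SNVs persist inside the candidate
deletion. The verdict is backed by a breakpoint scan for direct
repeats, including the rescan after applying one haplotype's SNVs,
which can extend an interrupted reference repeat into a long perfect
one on a single allele and thereby raise that allele's slippage
propensity.

Everything is testable without external data through a seeded diploid
amplicon simulator that reproduces the canonical scenario: an
11,941 bp product, a 2,599 bp candidate deletion (deleted form
9,342 bp), 28 bp breakpoint repeats extended by 8 haplotype SNVs, 5
het SNVs inside the deletion, and a 13/11/26 read composition.

## Worked example

```r
library(slipscan)

dir <- tempfile("fixture")
fx <- patient_fixture(dir)          # canonical seed-42 fixture, 50 reads

report <- run_artifact_check(
  fastq         = fx$paths$fastq,
  forms_fasta   = fx$paths$forms_fasta,
  candidate_del = "g.5001_7599del", # 2,599 bp candidate deletion
  scheme        = fx$paths$scheme,
  het_sites_file = fx$paths$het_sites)

report
#> == slipscan artifact check ==
#> reads: 50 input, 50 passed gates, 50 assigned+classified
#> verdict: artifact_suspected (3 allele classes)
#>   haplotype    form  n
#> 1      hapB deleted 26
#> 2      hapA  normal 13
#> 3      hapB  normal 11
#>  - 100% of 26 deletion-form reads carry haplotype hapB, shared with a full-length class
#>  - 5 heterozygous SNV(s) lie strictly inside the candidate deletion
#>  - direct repeat 33 bp on this allele (reference 14 bp), extended by haplotype SNVs (10 near the breakpoints); threshold 15 bp: elevated slippage propensity
#> deletion 4988-7587 (2599 bp, left-aligned)
#> reference direct repeat: 14 bp at 4986 / 7585 (1 mismatches)
#> haplotype direct repeat: 33 bp (25 SNVs applied)
#> spacer: 2566 bp
```

Reading the output: the 50 reads split into 24 full-length (13 on one
haplotype, 11 on the other) and 26 deletion-length reads that *all*
carry the minor full-length haplotype — three allele classes, which a
diploid locus cannot produce. Five heterozygous SNVs remain inside the
"deleted" interval, and on the suspect haplotype the breakpoint direct
repeat is more than twice its reference length, past the 15 bp
slippage-propensity threshold. Every line of evidence says PCR
artifact, not genomic deletion. On the true-deletion negative control
(`true_deletion_fixture()`) the same pipeline prints
`verdict: consistent (2 allele classes)`.

Variant triage utilities are included: `hgvs_del_length()`
(`g.6087520_6090118del` → 2599), `coding_consequence()` (c.7326 G>T in
a CAG codon → codon 2442, Gln→His, missense), `g_to_c()`/`c_to_g()`
coordinate arithmetic with intronic `+/-` offsets, and
`filter_candidates()` for the AF < 0.01 nonsynonymous rule against a
local allele-frequency table (see `inst/extdata/`).

A command-line wrapper with subcommands (`simulate`,
`validate-scheme`, `filter`, `assign`, `artifact-check`,
`scan-repeats`, `candidates`) ships in `inst/cli/slipscan`.

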