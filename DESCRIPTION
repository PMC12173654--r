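Package: slipscan
Title: Artifact Screening for Long-Range PCR Amplicon Nanopore Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quality control and artifact screening of long-range
    PCR tiling amplicons sequenced on long-read (nanopore) platforms, aimed
    at large repeat-laden genes such as VWF. Validates tiling-amplicon
    schemes, filters reads by quality and length, assigns reads to amplicons
    by 20-nt anchor sequences, bins reads into structural forms by length,
    genotypes individual reads at heterozygous SNVs to group them into
    haplotypes, and flags candidate deletions that are slipped-strand PCR
    artifacts via the three-allele haplotype incongruence signature together
    with direct-repeat breakpoint evidence. Includes HGVS coordinate
    arithmetic for variant triage against a local allele-frequency table and
    a seeded diploid amplicon simulator so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
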