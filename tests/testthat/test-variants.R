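test_that("HGVS range-deletion lengths are 1-based inclusive", {
  expect_identical(hgvs_del_length("NC_000012.12:g.6087520_6090118del"),
                   2599L)
  expect_identical(hgvs_del_length("g.100_100del"), 1L)
  expect_error(hgvs_del_length("g.200_100del"), "start > end")
  expect_error(hgvs_del_length("c.100_200del"), "cannot parse")
  withr::with_seed(81, {
    for (i in 1:25) {
      a <- sample.int(1e7, 1); b <- a + sample.int(5000, 1) - 1L
      expect_identical(hgvs_del_length(sprintf("g.%d_%ddel", a, b)),
                       as.integer(b - a + 1))
    }
  })
})

test_that("codon arithmetic annotates the glutamine-to-histidine change", {
  cds <- paste0(strrep("GCT", 2441), "CAG", "TAA")
  cc <- coding_consequence(7326, "G", "T", cds)
  expect_identical(cc$codon_index, 2442)
  expect_identical(cc$aa_ref, "Gln")
  expect_identical(cc$aa_alt, "His")
  expect_identical(cc$class, "missense")
  # first-codon change and a synonymous third-position change
  cds2 <- paste0("ATGGGG", strrep("GCT", 4), "TAA")
  cc2 <- coding_consequence(3, "G", "A", cds2)
  expect_identical(cc2[c("codon_index", "aa_ref", "aa_alt", "class")],
                   list(codon_index = 1, aa_ref = "Met", aa_alt = "Ile",
                        class = "missense"))
  expect_identical(coding_consequence(6, "G", "A", cds2)$class,
                   "synonymous")
  expect_error(coding_consequence(3, "T", "A", cds2), "mismatch")
})

test_that("single-codon consequence agrees with whole-CDS translation diff", {
  withr::with_seed(82, {
    for (i in 1:40) {
      n_codon <- 100L
      cds <- random_dna(3L * n_codon)
      p <- sample(3L * n_codon, 1)
      ref <- substring(cds, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      cc <- coding_consequence(p, ref, alt, cds)
      alt_cds <- cds
      substring(alt_cds, p, p) <- alt
      aa_ref <- oracle_translate(cds)
      aa_alt <- oracle_translate(alt_cds)
      diff <- which(aa_ref != aa_alt)
      if (length(diff) == 0L) {
        expect_identical(cc$class, "synonymous")
      } else {
        expect_identical(diff, as.integer(ceiling(p / 3)))
        expect_identical(cc$class,
                         if (aa_alt[diff] == "*") "nonsense" else "missense")
      }
    }
  })
})

toy_tx <- function(strand = "-") {
  # three exons; transcript order = decreasing genomic start on minus
  exons <- if (strand == "-")
    data.frame(start = c(700L, 400L, 100L), end = c(790L, 520L, 220L))
  else data.frame(start = c(100L, 400L, 700L), end = c(220L, 520L, 790L))
  transcript_model(exons, strand = strand)
}

test_that("genomic/coding mapping matches an exon-walk oracle on both strands", {
  for (strand in c("+", "-")) {
    tx <- toy_tx(strand)
    # oracle: enumerate exonic genomic positions in transcript order
    gpos <- unlist(lapply(seq_len(nrow(tx$exons)), function(i) {
      ex <- tx$exons[i, ]
      if (strand == "+") (ex$start + 1L):ex$end else ex$end:(ex$start + 1L)
    }))
    for (c_pos in c(1L, 50L, 121L, 200L, length(gpos))) {
      expect_identical(g_to_c(gpos[c_pos], tx)$c_pos, c_pos)
      expect_identical(g_to_c(gpos[c_pos], tx)$offset, 0L)
      expect_identical(c_to_g(c_pos, tx), gpos[c_pos])
    }
  }
})

test_that("intronic positions get HGVS +/- offsets off the nearest exon edge", {
  tx <- toy_tx("-")
  # 1 bp downstream (genomic) of the first minus-strand exon's start is
  # transcript-downstream: '+1' off that exon's last coding base (c.90)
  r <- g_to_c(700L, tx)
  expect_identical(r$text, "90+1")
  expect_identical(c_to_g(90L, tx, offset = 1L), 700L)
  # just genomic-above the second exon's end: '-1' off its first base
  r2 <- g_to_c(521L, tx)
  expect_identical(r2$text, "91-1")
  expect_error(g_to_c(5000L, tx), "outside")
})

test_that("g_to_c and c_to_g are mutually inverse on random toy transcripts", {
  withr::with_seed(83, {
    for (i in 1:20) {
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(2:5, 1)
      widths <- sample(30:90, n_ex, replace = TRUE) * 3L  # CDS %% 3 == 0
      gaps <- sample(30:200, n_ex, replace = TRUE)
      starts <- 1000L + cumsum(c(0L, (widths + gaps)[-n_ex]))
      exons <- data.frame(start = starts, end = starts + widths)
      if (strand == "-") exons <- exons[rev(seq_len(n_ex)), ]
      tx <- transcript_model(exons, strand = strand)
      for (c_pos in sample(tx$tx_len, 10)) {
        expect_identical(g_to_c(c_to_g(c_pos, tx), tx)$c_pos, c_pos)
      }
    }
  })
})

test_that("candidate filtering keeps rare nonsynonymous variants", {
  v <- data.frame(
    id = c("rare_mis", "common_mis", "rare_syn", "rare_nc", "noaf",
           "intron_sv"),
    consequence = c("missense", "missense", "synonymous", "non_coding",
                    "missense", "sv_del"),
    af = c(0.0049998, 0.2, 0.001, 0.001, NA, NA),
    region_class = c("exonic", "exonic", "exonic", "intronic", "exonic",
                     "intronic"),
    stringsAsFactors = FALSE)
  out <- filter_candidates(v)
  expect_identical(out$id, c("rare_mis", "noaf"))
  expect_identical(out$af_unverified, c(FALSE, TRUE))
  withi <- filter_candidates(v, include_intronic = TRUE)
  expect_true("intron_sv" %in% withi$id)
  expect_error(filter_candidates(transform(v, af = c(2, NA, NA, NA, NA, NA))),
               "outside")
})

test_that("lowering the AF threshold never adds candidates", {
  withr::with_seed(84, {
    v <- data.frame(
      consequence = sample(c("missense", "synonymous", "nonsense"),
                           200, replace = TRUE),
      af = ifelse(runif(200) < 0.1, NA, runif(200) ^ 3),
      stringsAsFactors = FALSE)
    thr <- sort(runif(8, 0, 0.5))
    counts <- vapply(thr, function(t)
      nrow(filter_candidates(v, af_threshold = t)), integer(1))
    expect_true(all(diff(counts) >= 0L))
  })
})

test_that("AF annotation joins on variant keys and flags unlisted variants", {
  af_file <- tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tref\talt\taf",
               "chr12\t5976222\tC\tA\t0.0049998"), af_file)
  tbl <- read_af_table(af_file)
  v <- data.frame(contig = "chr12", pos = c(5976222L, 6087520L),
                  ref = c("C", "T"), alt = c("A", "G"),
                  consequence = c("missense", "sv_del"),
                  stringsAsFactors = FALSE)
  v <- annotate_af(v, tbl)
  expect_equal(v$af, c(0.0049998, NA))
  out <- filter_candidates(v)
  expect_identical(out$af_unverified, c(FALSE, TRUE))
})

test_that("het sites round-trip through TSV and load from VCF", {
  s <- het_sites(c(10L, 99L), c("A", "C"), c("G", "T"))
  f <- tempfile(fileext = ".tsv")
  write_het_sites(s, f)
  expect_identical(read_het_sites(f)$pos, s$pos)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "amplicon\t11\t.\tA\tG\t50\tPASS\t.\tGT\t0|1",
    "amplicon\t100\t.\tC\tT\t50\tPASS\t.\tGT\t0|1"), vcf)
  got <- read_het_sites(vcf)
  expect_identical(got$pos, c(10L, 99L))
  expect_identical(got$allele_a, c("A", "C"))
  expect_identical(got$allele_b, c("G", "T"))
})
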