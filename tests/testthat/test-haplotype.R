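# small fully in-memory scenario built from the scaled-down locus
hap_scenario <- function(comp, seed = 7L, sub_error = 0,
                         locus = small_locus()) {
  sim <- simulate_reads(locus, comp, sub_error = sub_error,
                        indel_error = 0, orientation_frac = 1,
                        seed = seed)
  al <- align_reads_to_forms(sim$reads, locus$forms)
  list(locus = locus, reads = sim$reads, truth = sim$truth,
       alignments = al)
}

test_that("error-free reads genotype to their haplotype at every site", {
  sc <- hap_scenario(data.frame(haplotype = c("hapA", "hapB"),
                                form = "normal", count = 2L))
  gt <- genotype_reads(sc$reads, sc$alignments, sc$locus$forms,
                       sc$locus$sites)
  for (i in seq_len(nrow(sc$reads))) {
    want <- if (sc$truth$haplotype[i] == "hapA") "A" else "B"
    expect_identical(unname(gt[sc$truth$read_id[i], ]),
                     rep(want, nrow(sc$locus$sites)))
  }
})

test_that("sites inside the deletion are absent on deletion-form reads", {
  sc <- hap_scenario(data.frame(haplotype = "hapB", form = "deleted",
                                count = 2L))
  gt <- genotype_reads(sc$reads, sc$alignments, sc$locus$forms,
                       sc$locus$sites)
  inside <- sc$locus$sites$region == "inside_del"
  expect_identical(sum(inside), 3L)
  expect_true(all(gt[, inside] == "absent"))
  expect_true(all(gt[, !inside] == "B"))
})

test_that("a sequencing error at a site yields a single non-haplotype call", {
  locus <- small_locus()
  sites <- locus$sites
  seq <- locus$ref_seq  # pure hapA read
  p <- sites$pos[5] + 1L
  wrong <- setdiff(c("A", "C", "G", "T"),
                   c(sites$allele_a[5], sites$allele_b[5]))[1]
  substring(seq, p, p) <- wrong
  reads <- data.frame(id = "r1", seq = seq, stringsAsFactors = FALSE)
  al <- align_reads_to_forms(reads, locus$forms)
  gt <- genotype_reads(reads, al, locus$forms, sites)
  expect_identical(unname(gt[1, 5]), "other")
  expect_identical(unname(gt[1, -5]), rep("A", nrow(sites) - 1L))
})

test_that("haplotype vote applies informative-site and conflict thresholds", {
  expect_identical(assign_haplotype(rep("A", 8)), "hapA")
  expect_identical(assign_haplotype(c(rep("B", 4), "A")), "hapB")
  expect_identical(assign_haplotype(c(rep("B", 3), "A")), "ambiguous")
  expect_identical(assign_haplotype(rep("absent", 6)), "ambiguous")
  expect_identical(assign_haplotype(c("A", "B")), "ambiguous")
  expect_identical(assign_haplotype(c("A", "A", "other", "absent")),
                   "ambiguous")  # below min_informative
})

test_that("error-free reads with at least one informative site are always correctly haplotyped", {
  sc <- hap_scenario(data.frame(haplotype = c("hapA", "hapB", "hapB"),
                                form = c("normal", "normal", "deleted"),
                                count = c(5L, 5L, 5L)), seed = 12)
  gt <- genotype_reads(sc$reads, sc$alignments, sc$locus$forms,
                       sc$locus$sites)
  haps <- assign_haplotypes(gt, min_informative = 1L)
  expect_identical(unname(haps[sc$truth$read_id]), sc$truth$haplotype)
})

test_that("per-site genotyping accuracy tracks the substitution rate", {
  err <- 0.02
  sc <- hap_scenario(data.frame(haplotype = c("hapA", "hapB"),
                                form = "normal", count = 250L),
                     seed = 99, sub_error = err)
  gt <- genotype_reads(sc$reads, sc$alignments, sc$locus$forms,
                       sc$locus$sites)
  want <- ifelse(sc$truth$haplotype[match(rownames(gt),
                                          sc$truth$read_id)] == "hapA",
                 "A", "B")
  correct <- sweep(gt, 1, want, FUN = "==")
  acc <- mean(correct)
  n <- length(correct)
  # accuracy ~ Binomial(n, 1 - err); allow 3 SDs below the expectation
  expect_gte(acc, (1 - err) - 3 * sqrt(err * (1 - err) / n))
})

test_that("the three-allele signature is called artifact_suspected", {
  rt <- data.frame(
    read_id = sprintf("r%02d", 1:50),
    form_label = c(rep("normal", 24), rep("deleted", 26)),
    haplotype = c(rep("hapA", 13), rep("hapB", 11), rep("hapB", 26)),
    stringsAsFactors = FALSE)
  sites <- het_sites(c(100L, 6000L), c("A", "C"), c("G", "T"))
  v <- detect_incongruence(rt, c(5000, 7599), sites)
  expect_identical(v$verdict, "artifact_suspected")
  expect_identical(v$allele_class_count, 3L)
  expect_identical(v$n_het_inside_del, 1L)
})

test_that("a clean two-class partition with no interior SNV is consistent", {
  rt <- data.frame(
    read_id = sprintf("r%02d", 1:40),
    form_label = c(rep("normal", 20), rep("deleted", 20)),
    haplotype = c(rep("hapA", 20), rep("hapB", 20)),
    stringsAsFactors = FALSE)
  sites <- het_sites(c(100L, 9000L), c("A", "C"), c("G", "T"))
  v <- detect_incongruence(rt, c(5000, 7599), sites)
  expect_identical(v$verdict, "consistent")
  expect_identical(v$allele_class_count, 2L)
})

test_that("absence of deletion-form reads is an error, not a verdict", {
  rt <- data.frame(read_id = sprintf("r%02d", 1:40),
                   form_label = rep("normal", 40),
                   haplotype = rep("hapA", 40), stringsAsFactors = FALSE)
  sites <- het_sites(100L, "A", "G")
  expect_error(detect_incongruence(rt, c(5000, 7599), sites),
               "no candidate to evaluate")
})

test_that("the verdict is invariant to read order and haplotype label swap", {
  rt <- data.frame(
    read_id = sprintf("r%02d", 1:50),
    form_label = c(rep("normal", 24), rep("deleted", 26)),
    haplotype = c(rep("hapA", 13), rep("hapB", 11), rep("hapB", 26)),
    stringsAsFactors = FALSE)
  sites <- het_sites(6000L, "A", "G")
  base <- detect_incongruence(rt, c(5000, 7599), sites)
  withr::with_seed(8, shuffled <- rt[sample(nrow(rt)), ])
  v2 <- detect_incongruence(shuffled, c(5000, 7599), sites)
  swapped <- rt
  swapped$haplotype <- ifelse(rt$haplotype == "hapA", "hapB", "hapA")
  v3 <- detect_incongruence(swapped, c(5000, 7599), sites)
  for (v in list(v2, v3)) {
    expect_identical(v$verdict, base$verdict)
    expect_identical(v$allele_class_count, base$allele_class_count)
  }
})

test_that("interior het sites exclude the breakpoint bases", {
  rt <- data.frame(read_id = c("a", "b", "c", "d", "e", "f"),
                   form_label = rep(c("normal", "deleted"), 3),
                   haplotype = rep(c("hapA", "hapB"), 3),
                   stringsAsFactors = FALSE)
  # sites at the first and last deleted base do not count as interior
  sites <- het_sites(c(5000L, 7598L), c("A", "C"), c("G", "T"))
  v <- detect_incongruence(rt, c(5000, 7599), sites,
                           min_reads_per_class = 1L)
  expect_identical(v$n_het_inside_del, 0L)
  expect_identical(detect_incongruence(
    rt, c(5000, 7599), het_sites(5001L, "A", "G"),
    min_reads_per_class = 1L)$n_het_inside_del, 1L)
})

test_that("orientation-balanced subsampling is deterministic and warns on shortfall", {
  reads <- data.frame(id = sprintf("r%03d", 1:1000),
                      orientation = rep(c("forward", "reverse"),
                                        c(480, 520)),
                      stringsAsFactors = FALSE)
  s1 <- sample_reads(reads, 25, seed = 5)
  s2 <- sample_reads(reads, 25, seed = 5)
  expect_identical(s1, s2)
  expect_identical(as.vector(table(s1$orientation)), c(25L, 25L))
  small <- data.frame(id = sprintf("s%03d", 1:110),
                      orientation = rep(c("forward", "reverse"),
                                        c(10, 100)),
                      stringsAsFactors = FALSE)
  expect_warning(sub <- sample_reads(small, 25, seed = 5),
                 "only 10 forward")
  expect_identical(as.vector(table(sub$orientation)), c(10L, 25L))
})

test_that("the pileup caller recovers exactly the constructed het sites", {
  n_pos <- 200L
  n_reads <- 50L
  withr::with_seed(61, {
    cons <- sample(c("A", "C", "G", "T"), n_pos, replace = TRUE)
    site_idx <- sort(sample(n_pos, 8))
    alt <- vapply(cons[site_idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    mat <- matrix(rep(cons, each = n_reads), nrow = n_reads,
                  dimnames = list(sprintf("r%02d", 1:n_reads),
                                  0:(n_pos - 1L)))
    mat[27:50, site_idx] <- rep(alt, each = 24)  # hapB rows (minority)
  })
  called <- call_het_snvs(mat)
  expect_identical(called$pos, as.integer(site_idx - 1L))
  expect_equal(called$ab, rep(24 / 50, 8))
  # phased: allele_a belongs consistently to the hapA rows
  expect_identical(called$allele_a, unname(cons[site_idx]))
  expect_identical(called$allele_b, unname(alt))

  # 1% substitution noise neither loses sites nor invents them
  withr::with_seed(62, {
    noisy <- mat
    hit <- which(matrix(runif(length(mat)) < 0.01, nrow = n_reads))
    noisy[hit] <- vapply(noisy[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  })
  called2 <- call_het_snvs(noisy)
  expect_identical(called2$pos, as.integer(site_idx - 1L))

  # below the depth floor nothing is called
  expect_identical(nrow(call_het_snvs(mat[1:10, ])), 0L)
})
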