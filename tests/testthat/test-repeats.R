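# plant a repeat pair with copies abutting the deletion breakpoints:
# ... [copy1][spacer+copy2-deleted span] ... with copies one period apart
plant_repeat <- function(n, del_start, del_len, rep_len, seed) {
  withr::with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    copy <- sample(c("A", "C", "G", "T"), rep_len, replace = TRUE)
  })
  r1 <- del_start - rep_len
  r2 <- r1 + del_len
  chars[(r1 + 1):(r1 + rep_len)] <- copy
  chars[(r2 + 1):(r2 + rep_len)] <- copy
  # block chance extension at the outer edges
  chars[r1] <- setdiff(c("A", "C", "G", "T"), chars[r2])[1]
  chars[r2 + rep_len + 1] <- setdiff(c("A", "C", "G", "T"),
                                     chars[r1 + rep_len + 1])[1]
  paste(chars, collapse = "")
}

test_that("a planted exact 30 bp repeat flanking a 2599 bp deletion is found", {
  del <- c(5000L, 7599L)
  seq <- plant_repeat(11941L, del[1], 2599L, 30L, seed = 71)
  ctx <- find_direct_repeats(seq, del, max_mismatch_frac = 0)
  expect_identical(ctx$repeat_len_ref, 30L)
  expect_identical(ctx$spacer_len, 2599L - 30L)
  # matches the exhaustive oracle on the same (left-aligned) deletion
  la <- oracle_left_align(seq, del[1], del[2])
  want <- oracle_direct_repeats(seq, la[1], la[2], 300L, 0, 8L)
  expect_identical(ctx$repeat_len_ref, want$len)
})

test_that("random sequence without a planted repeat reports length 0", {
  withr::with_seed(72, seq <- random_dna(3000))
  ctx <- find_direct_repeats(seq, c(1000, 2000), window_bp = 150,
                             max_mismatch_frac = 0)
  want <- oracle_direct_repeats(seq, ctx$del_interval$start,
                                ctx$del_interval$end, 150L, 0, 8L)
  expect_identical(ctx$repeat_len_ref, want$len)
  expect_lt(ctx$repeat_len_ref, 8L)
})

test_that("scanner equals the exhaustive substring-pair oracle on random instances", {
  withr::with_seed(73, {
    for (i in 1:100) {
      n <- sample(500:2000, 1)
      del_len <- sample(100:300, 1)
      ds <- sample(120:(n - del_len - 120), 1)
      seq <- if (i %% 2 == 0) random_dna(n)
             else plant_repeat(n, ds, del_len,
                               sample(8:30, 1), seed = 7000 + i)
      frac <- sample(c(0, 0.1), 1)
      la <- oracle_left_align(seq, ds, ds + del_len)
      if (la[1] < 100 || la[2] + 100 > n) next
      ctx <- find_direct_repeats(seq, c(ds, ds + del_len),
                                 window_bp = 100,
                                 max_mismatch_frac = frac)
      want <- oracle_direct_repeats(seq, la[1], la[2], 100L, frac, 8L)
      expect_identical(ctx$repeat_len_ref, want$len)
      if (want$len > 0)
        expect_identical(ctx$mismatches, want$mismatches)
    }
  })
})

test_that("extending a planted repeat never shortens the reported length", {
  del <- c(2000L, 3000L)
  lens <- c(10L, 16L, 22L, 28L)
  got <- vapply(seq_along(lens), function(k) {
    seq <- plant_repeat(6000L, del[1], 1000L, lens[k], seed = 74)
    find_direct_repeats(seq, del, max_mismatch_frac = 0)$repeat_len_ref
  }, integer(1))
  expect_true(all(diff(got) >= 0L))
  expect_identical(got, lens)
})

test_that("scanning the reverse complement with mirrored coordinates gives the same length", {
  del <- c(2000L, 3000L)
  seq <- plant_repeat(6000L, del[1], 1000L, 20L, seed = 75)
  ctx <- find_direct_repeats(seq, del, max_mismatch_frac = 0)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  n <- nchar(seq)
  del_rc <- c(n - del[2], n - del[1])
  ctx_rc <- find_direct_repeats(rc, del_rc, max_mismatch_frac = 0)
  expect_identical(ctx_rc$repeat_len_ref, ctx$repeat_len_ref)
})

test_that("haplotype SNVs extend an interrupted repeat (constructed case)", {
  # copies of 28 bp agree on the breakpoint-proximal 12 bp core; the
  # left copy is interrupted at 8 positions which hapB reverts
  n <- 3000L; ds <- 1200L; dl <- 700L; rep_len <- 28L
  withr::with_seed(76, {
    chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    copy <- sample(c("A", "C", "G", "T"), rep_len, replace = TRUE)
  })
  r1 <- ds - rep_len; r2 <- r1 + dl
  snv_off <- seq(1L, by = 2L, length.out = 8L)  # inside the first 16 bp
  left <- copy
  left[snv_off + 1L] <- vapply(copy[snv_off + 1L], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  chars[(r1 + 1):(r1 + rep_len)] <- left
  chars[(r2 + 1):(r2 + rep_len)] <- copy
  chars[r1] <- setdiff(c("A", "C", "G", "T"), chars[r2])[1]
  chars[r2 + rep_len + 1] <- setdiff(c("A", "C", "G", "T"),
                                     chars[r1 + rep_len + 1])[1]
  seq <- paste(chars, collapse = "")
  hap_snvs <- data.frame(pos = r1 + snv_off,
                         ref = left[snv_off + 1L],
                         alt = copy[snv_off + 1L],
                         stringsAsFactors = FALSE)
  ctx <- apply_haplotype_and_rescan(seq, hap_snvs, c(ds, ds + dl),
                                    max_mismatch_frac = 0)
  expect_identical(ctx$repeat_len_ref, 12L)
  expect_identical(ctx$repeat_len_hap, 28L)
  # verified independently by the oracle on both sequences
  la <- oracle_left_align(seq, ds, ds + dl)
  expect_identical(oracle_direct_repeats(seq, la[1], la[2], 300L, 0,
                                         8L)$len, 12L)

  # no SNVs: haplotype scan is the identity
  ctx0 <- apply_haplotype_and_rescan(seq, hap_snvs[0, ], c(ds, ds + dl),
                                     max_mismatch_frac = 0)
  expect_identical(ctx0$repeat_len_hap, ctx0$repeat_len_ref)

  # an SNV far from both windows changes nothing
  far <- data.frame(pos = 100L,
                    ref = substring(seq, 101L, 101L),
                    alt = setdiff(c("A", "C", "G", "T"),
                                  substring(seq, 101L, 101L))[1],
                    stringsAsFactors = FALSE)
  ctx_far <- apply_haplotype_and_rescan(seq, far, c(ds, ds + dl),
                                        max_mismatch_frac = 0)
  expect_identical(ctx_far$repeat_len_hap, ctx$repeat_len_ref)

  # ref-base mismatch is an error naming the site
  bad <- hap_snvs; bad$ref[1] <- bad$alt[1]
  expect_error(apply_haplotype_and_rescan(seq, bad, c(ds, ds + dl)),
               as.character(bad$pos[1]))
})

test_that("slippage propensity flags long haplotype repeats", {
  ctx <- list(repeat_len_ref = 12L, repeat_len_hap = 28L,
              snvs_applied = data.frame(pos = 1:8),
              n_snvs_near_breakpoints = 8L)
  class(ctx) <- "repeat_context"
  p <- slippage_propensity(ctx)
  expect_identical(p$level, "elevated")
  expect_match(p$rationale, "28 bp")
  ctx$repeat_len_hap <- 12L
  expect_identical(slippage_propensity(ctx)$level, "low")
  ctx$repeat_len_ref <- 0L; ctx$repeat_len_hap <- 0L
  expect_identical(slippage_propensity(ctx)$level, "low")
})

test_that("deletions are left-aligned before scanning", {
  # AC|GTGT|AC...: deleting [2,4) or [4,6) gives the same sequence
  seq <- paste0("ACGTGT", strrep("ATCCGGAT", 100))
  la <- left_align_deletion(seq, c(4, 6))
  expect_identical(c(la$start, la$end), c(2L, 4L))
  expect_identical(c(la$start, la$end),
                   as.integer(oracle_left_align(seq, 4L, 6L)))
})

test_that("out-of-bounds deletions and thin flanks are errors", {
  withr::with_seed(77, seq <- random_dna(1000))
  expect_error(find_direct_repeats(seq, c(900, 1100)), "out of bounds")
  expect_error(find_direct_repeats(seq, c(100, 900), window_bp = 300),
               "flank")
})
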