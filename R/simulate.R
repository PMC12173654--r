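#' Build a synthetic diploid amplicon locus
#'
#' Constructs a seeded single-amplicon locus emulating a long-range PCR
#' product over a repeat-laden region: a full-length reference, a
#' deletion-bearing form, a direct-repeat pair whose copies abut the
#' deletion breakpoints and sit exactly one deletion length apart (the
#' slipped-strand geometry: deleting the interval merges the two copies
#' seamlessly), phased heterozygous SNVs on haplotype B that extend the
#' left repeat copy from an interrupted core to a full-length perfect
#' repeat, het SNVs strictly inside the deletion, flanking het SNVs on
#' both sides, and a 20-nt anchor near the 3' end for amplicon
#' assignment.
#'
#' Defaults mirror the canonical screening scenario: an 11,941 bp
#' product with a 2,599 bp candidate deletion, 28 bp repeat copies with
#' a 12 bp uninterrupted reference core, 8 repeat-extending hapB SNVs,
#' 5 het SNVs inside the deletion, and 12 flanking het SNVs.
#'
#' Haplotype A equals the reference at every het site; haplotype B
#' carries the alternate alleles.
#'
#' @param seed Integer seed; the locus is a pure function of its
#'   arguments.
#' @param ref_len Full-length form length (bp).
#' @param del_start 0-based start of the deletion.
#' @param del_len Deletion length (bp).
#' @param repeat_len Length of each direct-repeat copy (bp).
#' @param core_len Uninterrupted (reference-identical) core of the
#'   repeat, placed at the breakpoint-proximal end of each copy.
#' @param n_repeat_snvs hapB SNVs interrupting the reference repeat
#'   (all strictly left of the left breakpoint).
#' @param n_inside_snvs Het SNVs strictly inside the deletion.
#' @param n_flank_snvs Het SNVs outside the deletion (half per side).
#' @param anchor_seq Anchor planted near the 3' end.
#' @param anchor_offset_from_end Distance (bp) from anchor end to the 3'
#'   end of the product.
#' @return An object of class `sim_locus`: `ref_seq`, `del_interval`,
#'   `sites` (`het_sites` with `region` column), `hapB_snvs`,
#'   `repeat_spec`, `anchor`, `forms` (named list of
#'   [structural_form()]s), `scheme` (single-amplicon
#'   [amplicon_scheme()]).
#' @export
sim_locus <- function(seed = 42L, ref_len = 11941L, del_start = 5000L,
                      del_len = 2599L, repeat_len = 28L, core_len = 12L,
                      n_repeat_snvs = 8L, n_inside_snvs = 5L,
                      n_flank_snvs = 12L,
                      anchor_seq = "GACTTCCTGGTTCAAGGGAT",
                      anchor_offset_from_end = 480L) {
  del_end <- del_start + del_len
  anchor_seq <- toupper(anchor_seq)
  anchor_len <- nchar(anchor_seq)
  anchor_start <- ref_len - anchor_offset_from_end - anchor_len
  if (2L * n_repeat_snvs - 1L >= repeat_len - core_len)
    stop("repeat_len - core_len too small for n_repeat_snvs interruptions")
  if (del_len <= repeat_len || del_start <= repeat_len ||
      del_end + repeat_len >= anchor_start)
    stop("locus geometry inconsistent")

  bases <- c("A", "C", "G", "T")
  other_base <- function(b) vapply(b, function(x)
    sample(setdiff(bases, x), 1L), character(1), USE.NAMES = FALSE)

  withr::with_seed(as.integer(seed), {
    chars <- sample(bases, ref_len, replace = TRUE)

    # anchor: plant and keep it unique in the reference
    chars[(anchor_start + 1L):(anchor_start + anchor_len)] <-
      strsplit(anchor_seq, "")[[1L]]

    # direct-repeat copies abutting the breakpoints, one period apart:
    # R1 = [del_start - repeat_len, del_start), R2 = R1 + del_len
    r1 <- del_start - repeat_len  # 0-based start of left copy
    r2 <- r1 + del_len            # right copy (= del_end - repeat_len)
    snv_off <- seq.int(1L, by = 2L, length.out = n_repeat_snvs)
    hapB_repeat_base <- other_base(chars[r1 + snv_off + 1L])
    # ref right copy == hapB version of the left copy, so only hapB
    # carries an uninterrupted full-length repeat
    r2chars <- chars[(r1 + 1L):(r1 + repeat_len)]
    r2chars[snv_off + 1L] <- hapB_repeat_base
    chars[(r2 + 1L):(r2 + repeat_len)] <- r2chars
    # block chance extension of the planted pair at its outer edges
    chars[r1] <- other_base(chars[r2])
    if (r2 + repeat_len + 1L <= ref_len)
      chars[r2 + repeat_len + 1L] <- other_base(chars[r1 + repeat_len + 1L])

    repeat_pos <- r1 + snv_off
    inside_pos <- round(del_start + del_len *
                          seq(0.2, 0.8, length.out = n_inside_snvs))
    n_left <- ceiling(n_flank_snvs / 2); n_right <- n_flank_snvs - n_left
    left_pos <- round(seq(ref_len * 0.04, del_start - 200L,
                          length.out = n_left))
    right_pos <- round(seq(del_end + 200L,
                           anchor_start - 40L, length.out = n_right))
    pos <- as.integer(c(repeat_pos, inside_pos, left_pos, right_pos))
    region <- c(rep("repeat", length(repeat_pos)),
                rep("inside_del", length(inside_pos)),
                rep("flank", length(left_pos) + length(right_pos)))
    stopifnot(!anyDuplicated(pos))
    ref_allele <- chars[pos + 1L]
    alt_allele <- c(hapB_repeat_base,
                    other_base(chars[c(inside_pos, left_pos,
                                       right_pos) + 1L]))
    ref_seq <- paste(chars, collapse = "")
  })

  if (Biostrings::countPattern(anchor_seq,
                               Biostrings::DNAString(ref_seq)) != 1L)
    stop("anchor sequence is not unique in the simulated reference; ",
         "choose a different seed or anchor")

  sites <- het_sites(pos, ref_allele, alt_allele)
  sites$region <- region[order(pos)]

  deleted_seq <- paste0(substring(ref_seq, 1L, del_start),
                        substring(ref_seq, del_end + 1L, ref_len))
  del_iv <- genomic_interval("amplicon", del_start, del_end)
  forms <- list(
    normal = structural_form("normal", ref_seq),
    deleted = structural_form("deleted", deleted_seq,
                              del_interval = del_iv))

  amp <- amplicon("PCR21", "amplicon", 0L, ref_len,
                  anchor_seq = anchor_seq, anchor_end_window = 2000L)
  scheme <- amplicon_scheme(list(amp),
                            genomic_interval("amplicon", 0L, ref_len),
                            min_len_bp = 8000L, max_len_bp = 16000L,
                            min_overlap_bp = 0L, max_overlap_bp = ref_len)

  structure(list(
    ref_seq = ref_seq, del_interval = del_iv, sites = sites,
    hapA_snvs = sites[0, c("pos", "allele_a", "allele_b")],
    hapB_snvs = data.frame(pos = sites$pos, ref = sites$allele_a,
                           alt = sites$allele_b,
                           stringsAsFactors = FALSE),
    repeat_spec = list(left_start = r1, right_start = r2,
                       repeat_len = repeat_len, core_len = core_len,
                       n_repeat_snvs = n_repeat_snvs,
                       spacer_len = del_len - repeat_len),
    anchor = list(seq = anchor_seq, start = anchor_start),
    forms = forms, scheme = scheme, seed = as.integer(seed)),
    class = "sim_locus")
}

#' Write a simulated locus to disk
#'
#' Emits `forms.fasta` (both structural forms), `het_sites.tsv`,
#' `scheme.tsv` and `truth.json` (locus geometry) into a directory.
#'
#' @param locus A `sim_locus`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_locus <- function(locus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    forms_fasta = file.path(dir, "forms.fasta"),
    het_sites = file.path(dir, "het_sites.tsv"),
    scheme = file.path(dir, "scheme.tsv"),
    truth_json = file.path(dir, "truth.json"))
  fa <- Biostrings::DNAStringSet(c(
    normal = locus$forms$normal$ref_seq,
    deleted = locus$forms$deleted$ref_seq))
  Biostrings::writeXStringSet(fa, paths$forms_fasta)
  write_het_sites(locus$sites, paths$het_sites)
  write_scheme(locus$scheme, paths$scheme)
  truth <- list(
    seed = locus$seed,
    ref_len = nchar(locus$ref_seq),
    del_interval = c(locus$del_interval$start, locus$del_interval$end),
    n_het_sites = nrow(locus$sites),
    n_inside_del = sum(locus$sites$region == "inside_del"),
    n_repeat_snvs = sum(locus$sites$region == "repeat"),
    repeat_spec = locus$repeat_spec,
    anchor = locus$anchor)
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Simulate a long-range PCR amplicon pool with slipped-strand dropout
#'
#' Each template molecule of the extended-repeat haplotype (hapB)
#' independently becomes a deletion amplicon with probability
#' `slippage_rate_extended`; reference-repeat (hapA) molecules slip with
#' probability `slippage_rate_ref`. This end-point Bernoulli model
#' matches observed final amplicon proportions without simulating
#' per-cycle branching.
#'
#' @param locus A `sim_locus` (carried through for labels).
#' @param n_per_hap Named counts of template molecules,
#'   e.g. `c(hapA = 5000, hapB = 5000)`.
#' @param slippage_rate_extended P(deletion) per hapB molecule
#'   (default 0.70).
#' @param slippage_rate_ref P(deletion) per hapA molecule
#'   (default 0.05).
#' @param seed Integer seed.
#' @return Data frame with `molecule`, `haplotype`, `form`.
#' @export
simulate_pcr_pool <- function(locus,
                              n_per_hap = c(hapA = 5000L, hapB = 5000L),
                              slippage_rate_extended = 0.70,
                              slippage_rate_ref = 0.05, seed = 1L) {
  stopifnot(all(n_per_hap >= 0),
            slippage_rate_extended >= 0, slippage_rate_extended <= 1,
            slippage_rate_ref >= 0, slippage_rate_ref <= 1)
  hap <- rep(names(n_per_hap), n_per_hap)
  rate <- ifelse(hap == "hapB", slippage_rate_extended,
                 slippage_rate_ref)
  form <- withr::with_seed(as.integer(seed),
    ifelse(stats::runif(length(hap)) < rate, "deleted", "normal"))
  data.frame(molecule = seq_along(hap), haplotype = hap, form = form,
             stringsAsFactors = FALSE)
}

# internal: haplotype sequence of one (haplotype, form) molecule class
molecule_seq <- function(locus, haplotype, form) {
  chars <- strsplit(locus$ref_seq, "", fixed = TRUE)[[1L]]
  if (haplotype == "hapB")
    chars[locus$sites$pos + 1L] <- locus$sites$allele_b
  if (form == "deleted") {
    di <- locus$del_interval
    chars <- chars[-((di$start + 1L):di$end)]
  }
  paste(chars, collapse = "")
}

# internal: apply substitution and indel noise to one sequence
add_read_errors <- function(seq, sub_error, indel_error) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  n <- length(chars)
  if (sub_error > 0) {
    hit <- which(stats::runif(n) < sub_error)
    if (length(hit))
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1), USE.NAMES = FALSE)
  }
  if (indel_error > 0) {
    hit <- which(stats::runif(n) < indel_error)
    if (length(hit)) {
      is_ins <- stats::runif(length(hit)) < 0.5
      del_at <- hit[!is_ins]
      ins_at <- hit[is_ins]
      pieces <- as.list(chars)
      for (p in ins_at)
        pieces[[p]] <- c(pieces[[p]], sample(bases, 1L))
      if (length(del_at)) pieces[del_at] <- list(character(0))
      chars <- unlist(pieces)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate reads from a molecule composition with truth labels
#'
#' Generates one read per requested molecule: the haplotype sequence of
#' its (haplotype, form) class with substitution and indel errors,
#' random orientation, and a constant per-base quality consistent with
#' the substitution rate (`Q = -10 log10(sub_error)`, capped at 40 when
#' the rate is 0). Reads are shuffled so downstream code cannot rely on
#' input order.
#'
#' @param locus A `sim_locus`.
#' @param composition Data frame with `haplotype`, `form`, `count`
#'   (e.g. the 13/11/26 screening fixture), or a pool from
#'   [simulate_pcr_pool()] (its rows are tabulated).
#' @param sub_error Per-base substitution probability.
#' @param indel_error Per-base indel probability (insertions and
#'   deletions equally likely).
#' @param orientation_frac Probability a read is forward (default 0.5).
#' @param seed Integer seed.
#' @return List with `reads` (read table: `id`, `seq`, `qual`,
#'   `length_bp`, `mean_q`) and `truth` (`read_id`, `haplotype`,
#'   `form`, `orientation`).
#' @export
simulate_reads <- function(locus, composition, sub_error = 0.01,
                           indel_error = 0, orientation_frac = 0.5,
                           seed = 1L) {
  if (!"count" %in% names(composition)) {
    tab <- as.data.frame(table(haplotype = composition$haplotype,
                               form = composition$form),
                         stringsAsFactors = FALSE)
    composition <- tab[tab$Freq > 0L, , drop = FALSE]
    names(composition)[names(composition) == "Freq"] <- "count"
  }
  class_seqs <- mapply(function(h, f) molecule_seq(locus, h, f),
                       composition$haplotype, composition$form,
                       SIMPLIFY = TRUE)
  hap <- rep(composition$haplotype, composition$count)
  form <- rep(composition$form, composition$count)
  tmpl <- rep(class_seqs, composition$count)
  n <- length(tmpl)
  q <- if (sub_error > 0) max(2L, round(-10 * log10(sub_error))) else 40L

  withr::with_seed(as.integer(seed), {
    orient <- ifelse(stats::runif(n) < orientation_frac,
                     "forward", "reverse")
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- add_read_errors(tmpl[i], sub_error, indel_error)
      if (orient[i] == "reverse")
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      seqs[i] <- s
    }
    ord <- sample.int(n)
  })

  ids <- sprintf("read%04d", seq_len(n))
  reads <- data.frame(
    id = ids, seq = seqs[ord],
    qual = vapply(nchar(seqs[ord]), function(L)
      paste(rep(rawToChar(as.raw(q + 33L)), L), collapse = ""),
      character(1)),
    length_bp = nchar(seqs[ord]),
    stringsAsFactors = FALSE)
  reads$mean_q <- mean_read_quality(reads$qual)
  truth <- data.frame(read_id = ids, haplotype = hap[ord],
                      form = form[ord], orientation = orient[ord],
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' The canonical slipped-strand screening fixture
#'
#' Generates the package's regression scenario end to end: the default
#' [sim_locus()], 50 reads in the 13 hapA-normal / 11 hapB-normal / 26
#' hapB-deleted composition (the three-allele signature: every
#' deletion-form read shares the minor full-length haplotype), 1%
#' substitution error, and writes FASTQ, forms FASTA, het-site TSV,
#' scheme TSV, truth TSV and truth JSON into `dir`.
#'
#' @param dir Output directory.
#' @param seed Fixture seed (default 42; the fixture is defined by this
#'   seed and is bit-reproducible).
#' @return List with `paths`, `locus`, `reads`, `truth`.
#' @export
patient_fixture <- function(dir = tempfile("fixture"), seed = 42L) {
  locus <- sim_locus(seed = seed)
  composition <- data.frame(
    haplotype = c("hapA", "hapB", "hapB"),
    form = c("normal", "normal", "deleted"),
    count = c(13L, 11L, 26L), stringsAsFactors = FALSE)
  sim <- simulate_reads(locus, composition, sub_error = 0.01,
                        indel_error = 0, seed = seed + 1L)
  paths <- write_locus(locus, dir)
  paths$fastq <- file.path(dir, "reads.fastq")
  write_fastq(sim$reads, paths$fastq)
  paths$truth_tsv <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, paths$truth_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(paths = paths, locus = locus, reads = sim$reads,
       truth = sim$truth)
}

#' A true heterozygous deletion fixture (negative control)
#'
#' Same locus family as [patient_fixture()] but with a genuine deletion:
#' no het SNVs inside the deleted span, all hapB molecules deleted and
#' all hapA molecules full length, so the expected verdict is
#' `consistent` with exactly two allele classes.
#'
#' @param dir Output directory.
#' @param seed Fixture seed (default 43).
#' @param n_per_class Reads per class (default 20 + 20).
#' @return List with `paths`, `locus`, `reads`, `truth`.
#' @export
true_deletion_fixture <- function(dir = tempfile("truedel"), seed = 43L,
                                  n_per_class = 20L) {
  locus <- sim_locus(seed = seed, n_inside_snvs = 0L)
  composition <- data.frame(
    haplotype = c("hapA", "hapB"),
    form = c("normal", "deleted"),
    count = rep(as.integer(n_per_class), 2L), stringsAsFactors = FALSE)
  sim <- simulate_reads(locus, composition, sub_error = 0.01,
                        indel_error = 0, seed = seed + 1L)
  paths <- write_locus(locus, dir)
  paths$fastq <- file.path(dir, "reads.fastq")
  write_fastq(sim$reads, paths$fastq)
  paths$truth_tsv <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, paths$truth_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(paths = paths, locus = locus, reads = sim$reads,
       truth = sim$truth)
}
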