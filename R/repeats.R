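#' Left-align a deletion within repetitive context
#'
#' A deletion flanked by a repeat is shiftable: deleting `[s, e)` gives
#' the same sequence as deleting `[s-1, e-1)` whenever the base before the
#' deletion equals the last deleted base. Following VCF normalization
#' convention, deletions are shifted as far left as possible before
#' breakpoint analysis so the scan is invariant to how the caller placed
#' the breakpoints.
#'
#' @param seq Sequence (character).
#' @param del_interval Deletion, 0-based half-open.
#' @return The left-aligned `genomic_interval`.
#' @export
left_align_deletion <- function(seq, del_interval) {
  del <- as_interval(del_interval)
  s <- del$start; e <- del$end
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  while (s > 0L && chars[s] == chars[e]) {  # chars[s] = base before del
    s <- s - 1L; e <- e - 1L
  }
  genomic_interval(del$contig, s, e)
}

#' Find direct repeats flanking deletion breakpoints
#'
#' Searches for the longest pair of same-strand (direct) repeat copies,
#' compared without indels and allowing at most `max_mismatch_frac`
#' mismatches, such that one copy starts within `window_bp` of the left
#' breakpoint and overlaps or abuts it, and the other does the same at
#' the right breakpoint. Such a repeat-spacer-repeat arrangement is the
#' substrate for slipped-strand mispairing during long-range PCR, which
#' excises the spacer plus one repeat copy and yields artifactual
#' deletion amplicons.
#'
#' @param ref_seq Reference (or haplotype) sequence containing the
#'   deletion.
#' @param del_interval Candidate deletion, 0-based half-open
#'   (`genomic_interval` or `c(start, end)`); left-aligned before
#'   scanning.
#' @param window_bp Breakpoint window for repeat starts (default 300).
#' @param max_mismatch_frac Mismatch tolerance as a fraction of repeat
#'   length (default 0.1).
#' @param min_repeat_len Minimum reportable repeat length (default 8);
#'   below it the context reports length 0.
#' @return A `repeat_context` list: `del_interval` (left-aligned),
#'   `repeat_len_ref`, `repeat_seq_ref`, `left_start`, `right_start`,
#'   `mismatches`, `spacer_len`, plus the scan parameters. Haplotype
#'   fields are filled by [apply_haplotype_and_rescan()].
#' @export
find_direct_repeats <- function(ref_seq, del_interval, window_bp = 300L,
                                max_mismatch_frac = 0.1,
                                min_repeat_len = 8L) {
  ref_seq <- toupper(as.character(ref_seq))
  del <- as_interval(del_interval)
  n <- nchar(ref_seq)
  if (del$start < 0L || del$end > n)
    stop("deletion interval out of bounds")
  del <- left_align_deletion(ref_seq, del)
  if (del$start - window_bp < 0L || del$end + window_bp > n)
    stop("need at least window_bp flanking sequence on each side of the deletion")
  hit <- .scan_direct_repeats_cpp(ref_seq, del$start, del$end,
                                  as.integer(window_bp),
                                  max_mismatch_frac,
                                  as.integer(min_repeat_len))
  len <- hit$len
  ctx <- list(
    del_interval = del,
    repeat_len_ref = len,
    repeat_seq_ref = if (len > 0L)
      substring(ref_seq, hit$left_start + 1L, hit$left_start + len) else "",
    left_start = if (len > 0L) hit$left_start else NA_integer_,
    right_start = if (len > 0L) hit$right_start else NA_integer_,
    mismatches = hit$mismatches,
    spacer_len = if (len > 0L) interval_width(del) - len else NA_integer_,
    repeat_len_hap = NA_integer_,
    repeat_seq_hap = NA_character_,
    snvs_applied = data.frame(pos = integer(0), ref = character(0),
                              alt = character(0),
                              stringsAsFactors = FALSE),
    window_bp = as.integer(window_bp),
    max_mismatch_frac = max_mismatch_frac,
    min_repeat_len = as.integer(min_repeat_len))
  class(ctx) <- "repeat_context"
  ctx
}

#' Rescan for direct repeats after applying one haplotype's SNVs
#'
#' Substitutes a haplotype's alleles into the reference sequence and
#' repeats the breakpoint scan, reporting the reference and haplotype
#' repeat lengths side by side. Heterozygous SNVs close to a breakpoint
#' can convert an interrupted, inert repeat into a long uninterrupted one
#' on a single allele, raising that allele's slippage propensity.
#'
#' @param ref_seq Reference sequence.
#' @param hap_snvs Data frame with `pos` (0-based), `ref`, `alt`: the
#'   haplotype's substitutions relative to `ref_seq`.
#' @param del_interval Candidate deletion (0-based half-open).
#' @param ... Passed to [find_direct_repeats()].
#' @return A `repeat_context` with both `repeat_len_ref` and
#'   `repeat_len_hap` populated and `snvs_applied` recorded.
#' @export
apply_haplotype_and_rescan <- function(ref_seq, hap_snvs, del_interval,
                                       ...) {
  ref_seq <- toupper(as.character(ref_seq))
  ctx <- find_direct_repeats(ref_seq, del_interval, ...)
  chars <- strsplit(ref_seq, "", fixed = TRUE)[[1L]]
  if (nrow(hap_snvs) > 0L) {
    pos1 <- as.integer(hap_snvs$pos) + 1L
    bad <- chars[pos1] != toupper(hap_snvs$ref)
    if (any(bad))
      stop("SNV ref base mismatch at position(s) ",
           paste(hap_snvs$pos[bad], collapse = ", "))
    chars[pos1] <- toupper(hap_snvs$alt)
  }
  hap_seq <- paste(chars, collapse = "")
  hap_ctx <- find_direct_repeats(hap_seq, del_interval, ...)
  ctx$repeat_len_hap <- hap_ctx$repeat_len_ref
  ctx$repeat_seq_hap <- hap_ctx$repeat_seq_ref
  ctx$hap_left_start <- hap_ctx$left_start
  ctx$hap_right_start <- hap_ctx$right_start
  ctx$hap_del_interval <- hap_ctx$del_interval
  ctx$spacer_len <- if (hap_ctx$repeat_len_ref > 0L)
    interval_width(hap_ctx$del_interval) - hap_ctx$repeat_len_ref
    else ctx$spacer_len
  ctx$snvs_applied <- hap_snvs
  # SNVs close enough to a breakpoint to have shaped the repeat
  win <- ctx$window_bp
  d <- ctx$del_interval
  near <- (hap_snvs$pos >= d$start - win & hap_snvs$pos <= d$start + win) |
    (hap_snvs$pos >= d$end - win & hap_snvs$pos <= d$end + win)
  ctx$n_snvs_near_breakpoints <- sum(near)
  ctx
}

#' Slippage propensity verdict for a repeat context
#'
#' Flags a deletion's breakpoint context as `elevated` when the
#' haplotype-level direct repeat reaches `flag_min_len`; short repeats,
#' like those present in the unmodified reference of most loci, have
#' little effect on long-range PCR.
#'
#' @param ctx A `repeat_context` (if `repeat_len_hap` is NA, the
#'   reference length is used, i.e. the allele equals the reference).
#' @param flag_min_len Minimum repeat length considered slippage-prone
#'   (default 15).
#' @return List with `level` (`"low"`/`"elevated"`) and `rationale`.
#' @export
slippage_propensity <- function(ctx, flag_min_len = 15L) {
  hap_len <- if (is.na(ctx$repeat_len_hap)) ctx$repeat_len_ref
             else ctx$repeat_len_hap
  level <- if (hap_len >= flag_min_len) "elevated" else "low"
  extended <- !is.na(ctx$repeat_len_hap) &&
    ctx$repeat_len_hap > ctx$repeat_len_ref
  n_near <- if (!is.null(ctx$n_snvs_near_breakpoints))
    ctx$n_snvs_near_breakpoints else nrow(ctx$snvs_applied)
  rationale <- sprintf(
    "direct repeat %d bp on this allele (reference %d bp)%s; threshold %d bp: %s slippage propensity",
    hap_len, ctx$repeat_len_ref,
    if (extended)
      sprintf(", extended by haplotype SNVs (%d near the breakpoints)",
              n_near)
    else "",
    flag_min_len, level)
  list(level = level, rationale = rationale)
}

#' @export
print.repeat_context <- function(x, ...) {
  cat(sprintf("deletion %d-%d (%d bp, left-aligned)\n",
              x$del_interval$start, x$del_interval$end,
              interval_width(x$del_interval)))
  cat(sprintf("reference direct repeat: %d bp", x$repeat_len_ref))
  if (x$repeat_len_ref > 0L)
    cat(sprintf(" at %d / %d (%d mismatches)", x$left_start,
                x$right_start, x$mismatches))
  cat("\n")
  if (!is.na(x$repeat_len_hap))
    cat(sprintf("haplotype direct repeat: %d bp (%d SNVs applied)\n",
                x$repeat_len_hap, nrow(x$snvs_applied)))
  if (!is.na(x$spacer_len))
    cat(sprintf("spacer: %d bp\n", x$spacer_len))
  invisible(x)
}
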