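# Independent brute-force oracles and small generators used across tests.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# exhaustive substring-pair direct-repeat scan (mirrors the documented
# rules by direct enumeration; vectorised per start pair)
oracle_direct_repeats <- function(seq, del_start, del_end, window,
                                  frac, min_len) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  best_len <- 0L; best_mm <- NA_integer_
  for (i in max(0L, del_start - window):del_start) {
    j_lo <- max(max(0L, del_end - window), i + 1L)
    if (j_lo > del_end) next
    for (j in j_lo:min(del_end, n - 1L)) {
      lcap <- min(j - i, n - j)
      if (lcap < 1L) next
      mm <- cumsum(chars[(i + 1L):(i + lcap)] !=
                     chars[(j + 1L):(j + lcap)])
      L <- seq_len(lcap)
      valid <- mm <= floor(frac * L) & L >= min_len &
        (i + L) >= del_start & (j + L) >= del_end
      if (!any(valid)) next
      Lbest <- max(L[valid])
      if (Lbest > best_len ||
          (Lbest == best_len && mm[Lbest] < best_mm)) {
        best_len <- Lbest
        best_mm <- mm[Lbest]
      }
    }
  }
  if (best_len < min_len) list(len = 0L, mismatches = 0L)
  else list(len = best_len, mismatches = best_mm)
}

# left-align a 0-based half-open deletion (independent re-derivation)
oracle_left_align <- function(seq, s, e) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  while (s > 0L && chars[s] == chars[e]) { s <- s - 1L; e <- e - 1L }
  c(s, e)
}

# brute-force scheme validation: per-base coverage sweep + direct loops
oracle_validate_scheme <- function(scheme) {
  amps <- scheme$amplicons
  tgt <- scheme$target
  viol <- list()
  for (a in amps) {
    w <- a$expected_len_bp
    if (w < scheme$min_len_bp || w > scheme$max_len_bp)
      viol[[length(viol) + 1L]] <- c("size_out_of_range",
                                     a$interval$start, a$interval$end)
  }
  covered <- rep(FALSE, interval_width(tgt))
  for (a in amps) {
    if (a$interval$contig != tgt$contig) next
    lo <- max(a$interval$start, tgt$start) - tgt$start
    hi <- min(a$interval$end, tgt$end) - tgt$start
    if (hi > lo) covered[(lo + 1L):hi] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  for (k in seq_along(r$values)) {
    if (!r$values[k])
      viol[[length(viol) + 1L]] <- c("gap", tgt$start + starts[k],
                                     tgt$start + ends[k])
  }
  if (length(amps) > 1L) {
    prev <- amps[[1L]]
    for (i in 2L:length(amps)) {
      cur <- amps[[i]]
      if (cur$interval$end <= prev$interval$end) next
      ov <- prev$interval$end - cur$interval$start
      if (ov >= 0L && (ov < scheme$min_overlap_bp ||
                       ov > scheme$max_overlap_bp))
        viol[[length(viol) + 1L]] <- c(
          "overlap_out_of_range",
          min(cur$interval$start, prev$interval$end),
          max(cur$interval$start, prev$interval$end))
      prev <- cur
    }
  }
  if (!length(viol))
    return(data.frame(type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  df <- as.data.frame(do.call(rbind, viol), stringsAsFactors = FALSE)
  names(df) <- c("type", "start", "end")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df[order(df$start, df$end, df$type), , drop = FALSE]
}

# small scaled-down locus for alignment-heavy tests
small_locus <- function(seed = 7L, ...) {
  sim_locus(seed = seed, ref_len = 3000L, del_start = 1200L,
            del_len = 700L, n_inside_snvs = 3L, n_flank_snvs = 8L,
            anchor_offset_from_end = 280L, ...)
}

# translate a CDS codon-by-codon with the standard code (oracle for
# consequence classification; tolerates internal stops)
oracle_translate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  unname(Biostrings::GENETIC_CODE[codons])
}
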