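#' Define a tiling amplicon
#'
#' An amplicon is one long-range PCR product in a tiling scheme. The
#' optional anchor is a short (typically 20 nt) subsequence that occurs
#' once in the amplicon and, for the amplicon it identifies, lies close to
#' one product end; reads are assigned to amplicons by locating the anchor
#' (or its reverse complement) near a read end.
#'
#' @param id Unique amplicon identifier.
#' @param contig Contig the amplicon lies on.
#' @param start,end 0-based half-open genomic bounds of the product.
#' @param anchor_seq Optional anchor sequence (uppercased; ACGT only).
#' @param anchor_end_window Window (bp) from a read end within which the
#'   anchor must fall for the read to be assigned here. Default 2000 bp,
#'   wide enough to catch an anchor a few hundred bases from the product
#'   end while rejecting mid-read occurrences in overlapping amplicons.
#' @return An object of class `amplicon`.
#' @export
amplicon <- function(id, contig, start, end, anchor_seq = NULL,
                     anchor_end_window = 2000L) {
  iv <- genomic_interval(contig, start, end)
  if (!is.null(anchor_seq)) {
    anchor_seq <- toupper(anchor_seq)
    if (!grepl("^[ACGT]+$", anchor_seq))
      stop("anchor_seq must contain only A/C/G/T")
  }
  structure(list(id = as.character(id), interval = iv,
                 expected_len_bp = interval_width(iv),
                 anchor_seq = anchor_seq,
                 anchor_end_window_bp = as.integer(anchor_end_window)),
            class = "amplicon")
}

#' Assemble a tiling-amplicon scheme
#'
#' A scheme is an ordered set of amplicons tiling a target locus, with
#' product-size and adjacent-overlap constraints and optional off-target
#' intervals (e.g. a homologous pseudogene region) monitored for
#' specificity. Defaults reflect a 12-15 kb product design with 3-8 kb
#' overlaps between adjacent products.
#'
#' @param amplicons List of [amplicon()] objects (any order; sorted by start).
#' @param target `genomic_interval` the scheme must cover.
#' @param off_targets List of `genomic_interval`s that must stay uncovered.
#' @param min_len_bp,max_len_bp Allowed product length range (bp).
#' @param min_overlap_bp,max_overlap_bp Allowed adjacent-overlap range (bp).
#' @return An object of class `amplicon_scheme`.
#' @export
amplicon_scheme <- function(amplicons, target, off_targets = list(),
                            min_len_bp = 12000L, max_len_bp = 15000L,
                            min_overlap_bp = 3000L, max_overlap_bp = 8000L) {
  if (length(amplicons) == 0L) stop("empty scheme")
  if (!all(vapply(amplicons, inherits, logical(1), "amplicon")))
    stop("amplicons must be a list of amplicon objects")
  ids <- vapply(amplicons, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("amplicon ids must be unique")
  starts <- vapply(amplicons, function(a) a$interval$start, integer(1))
  ends <- vapply(amplicons, function(a) a$interval$end, integer(1))
  amplicons <- amplicons[order(starts, ends)]
  structure(list(amplicons = amplicons, target = target,
                 off_targets = off_targets,
                 min_len_bp = as.integer(min_len_bp),
                 max_len_bp = as.integer(max_len_bp),
                 min_overlap_bp = as.integer(min_overlap_bp),
                 max_overlap_bp = as.integer(max_overlap_bp)),
            class = "amplicon_scheme")
}

#' Read a tiling scheme from a TSV file
#'
#' Expected columns: `id`, `contig`, `start`, `end` (0-based half-open),
#' optional `anchor_seq` and `anchor_end_window`. Lines starting with `#`
#' are ignored.
#'
#' @param path TSV file path.
#' @param target Optional `genomic_interval`; defaults to the span of the
#'   amplicons on the first contig.
#' @param ... Passed to [amplicon_scheme()] (constraint bounds, off-targets).
#' @return An `amplicon_scheme`.
#' @export
read_scheme <- function(path, target = NULL, ...) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("id", "contig", "start", "end")
  if (!all(need %in% names(df)))
    stop("scheme file must have columns id, contig, start, end")
  if (!"anchor_seq" %in% names(df)) df$anchor_seq <- NA_character_
  if (!"anchor_end_window" %in% names(df)) df$anchor_end_window <- 2000L
  amps <- lapply(seq_len(nrow(df)), function(i) {
    anc <- df$anchor_seq[i]
    if (is.na(anc) || !nzchar(anc)) anc <- NULL
    amplicon(df$id[i], df$contig[i], df$start[i], df$end[i],
             anchor_seq = anc, anchor_end_window = df$anchor_end_window[i])
  })
  if (is.null(target))
    target <- genomic_interval(df$contig[1], min(df$start), max(df$end))
  amplicon_scheme(amps, target, ...)
}

#' Write a tiling scheme to TSV
#' @param scheme An `amplicon_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  df <- data.frame(
    id = vapply(scheme$amplicons, `[[`, character(1), "id"),
    contig = vapply(scheme$amplicons, function(a) a$interval$contig,
                    character(1)),
    start = vapply(scheme$amplicons, function(a) a$interval$start,
                   integer(1)),
    end = vapply(scheme$amplicons, function(a) a$interval$end, integer(1)),
    anchor_seq = vapply(scheme$amplicons, function(a)
      if (is.null(a$anchor_seq)) "" else a$anchor_seq, character(1)),
    anchor_end_window = vapply(scheme$amplicons, `[[`, integer(1),
                               "anchor_end_window_bp"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a tiling scheme against its design constraints
#'
#' Checks that (i) every amplicon length lies within the scheme's product
#' size range, (ii) the union of amplicon intervals covers the target with
#' no gaps, and (iii) every pair of consecutive amplicons (after sorting by
#' start) overlaps within the allowed range. An amplicon fully contained in
#' its predecessor is treated as a deliberate redundant (bridge) product
#' and is exempt from the overlap check.
#'
#' @param scheme An `amplicon_scheme`.
#' @return A `scheme_report`: data frame of violations with columns
#'   `type` (`gap`, `size_out_of_range`, `overlap_out_of_range`),
#'   `start`, `end`, `amplicons`, ordered by coordinate. Zero rows means
#'   the scheme satisfies all constraints.
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "amplicon_scheme"))
  amps <- scheme$amplicons
  if (length(amps) == 0L) stop("empty scheme")
  viol <- list()

  # product sizes
  for (a in amps) {
    w <- a$expected_len_bp
    if (w < scheme$min_len_bp || w > scheme$max_len_bp)
      viol[[length(viol) + 1L]] <- data.frame(
        type = "size_out_of_range", start = a$interval$start,
        end = a$interval$end, amplicons = a$id, stringsAsFactors = FALSE)
  }

  # coverage gaps over the target
  tgt <- scheme$target
  ivs <- lapply(amps, `[[`, "interval")
  on_target <- Filter(function(iv)
    iv$contig == tgt$contig && iv$end > tgt$start && iv$start < tgt$end, ivs)
  cover_end <- tgt$start
  for (iv in on_target) {  # already sorted by start
    if (iv$start > cover_end) {
      viol[[length(viol) + 1L]] <- data.frame(
        type = "gap", start = cover_end, end = iv$start, amplicons = "",
        stringsAsFactors = FALSE)
    }
    cover_end <- max(cover_end, iv$end)
  }
  if (cover_end < tgt$end)
    viol[[length(viol) + 1L]] <- data.frame(
      type = "gap", start = cover_end, end = tgt$end, amplicons = "",
      stringsAsFactors = FALSE)

  # adjacent overlaps (consecutive after sorting; contained => redundant)
  if (length(amps) > 1L) {
    prev <- amps[[1L]]
    for (i in 2L:length(amps)) {
      cur <- amps[[i]]
      if (cur$interval$contig != prev$interval$contig) { prev <- cur; next }
      if (cur$interval$end <= prev$interval$end) next  # contained: bridge
      ov <- prev$interval$end - cur$interval$start
      if (ov >= 0L && (ov < scheme$min_overlap_bp ||
                       ov > scheme$max_overlap_bp))
        viol[[length(viol) + 1L]] <- data.frame(
          type = "overlap_out_of_range",
          start = min(cur$interval$start, prev$interval$end),
          end = max(cur$interval$start, prev$interval$end),
          amplicons = paste(prev$id, cur$id, sep = ","),
          stringsAsFactors = FALSE)
      prev <- cur
    }
  }

  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(type = character(0), start = integer(0), end = integer(0),
               amplicons = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end, out$type), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scheme_report", class(out))
  out
}

#' @export
print.scheme_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("scheme OK: no violations\n")
  } else {
    cat(sprintf("scheme has %d violation(s):\n", nrow(x)))
    print.data.frame(x)
  }
  invisible(x)
}

#' On/off-target specificity verdict from per-base depths
#'
#' Passes when the maximum depth over the off-target (e.g. pseudogene)
#' intervals is strictly below the minimum depth over the target locus, so
#' that even the worst-covered target base outreads the best-covered
#' off-target base.
#'
#' @param on_depth Numeric vector of per-base depth over the target.
#' @param off_depth Numeric vector of per-base depth over the off-target
#'   intervals (may be empty, in which case `max_off` is reported as 0).
#' @return A list of class `qc_verdict` with `pass`, `min_on`, `max_off`.
#' @export
off_target_specificity <- function(on_depth, off_depth = numeric(0)) {
  if (length(on_depth) == 0L) stop("empty target depth")
  if (any(on_depth < 0) || any(off_depth < 0))
    stop("depths must be non-negative")
  min_on <- min(on_depth)
  max_off <- if (length(off_depth)) max(off_depth) else 0
  structure(list(pass = max_off < min_on, min_on = min_on,
                 max_off = max_off),
            class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("specificity %s: min on-target depth %g, max off-target %g\n",
              if (x$pass) "PASS" else "FAIL", x$min_on, x$max_off))
  invisible(x)
}

#' Per-base depth over an interval from read-to-amplicon assignments
#'
#' Simplified depth model: each assigned read contributes one unit of depth
#' over its amplicon's full interval (no base-level alignment). Off-target
#' depth from external mapping can be passed to
#' [off_target_specificity()] directly instead.
#'
#' @param assignments Data frame with an `amplicon_id` column (NA for
#'   unassigned reads), as produced by [assign_amplicon()].
#' @param scheme The `amplicon_scheme`.
#' @param interval Interval over which to compute depth (default: the
#'   scheme's target).
#' @return Numeric vector of length `interval_width(interval)`.
#' @export
depth_from_assignments <- function(assignments, scheme,
                                   interval = scheme$target) {
  depth <- numeric(interval_width(interval))
  counts <- table(assignments$amplicon_id)
  for (a in scheme$amplicons) {
    n <- counts[a$id]
    if (is.na(n) || n == 0L) next
    if (a$interval$contig != interval$contig) next
    lo <- max(a$interval$start, interval$start) - interval$start
    hi <- min(a$interval$end, interval$end) - interval$start
    if (hi > lo) depth[(lo + 1L):hi] <- depth[(lo + 1L):hi] + as.integer(n)
  }
  depth
}
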