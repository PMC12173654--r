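#' Read a FASTQ file into a read table
#'
#' Loads long reads with their per-base qualities and computes the mean
#' read quality as `-10*log10(mean per-base error probability)`, the
#' convention used by long-read filtering tools, so a read's quality is
#' dominated by its worst bases rather than the arithmetic mean of Phred
#' scores.
#'
#' @param path FASTQ file (plain or gzip).
#' @return Data frame with columns `id`, `seq`, `qual`, `length_bp`,
#'   `mean_q`.
#' @export
read_fastq <- function(path) {
  qs <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(qs))
  seqs <- as.character(qs)
  quals <- as.character(Biostrings::quality(qs))
  data.frame(id = ids, seq = unname(seqs), qual = unname(quals),
             length_bp = nchar(unname(seqs)),
             mean_q = mean_read_quality(quals),
             stringsAsFactors = FALSE)
}

#' Mean read quality from Phred quality strings
#' @param qual Character vector of Phred+33 quality strings.
#' @return Numeric vector of mean read qualities.
#' @export
mean_read_quality <- function(qual) {
  vapply(qual, function(q) {
    ph <- utf8ToInt(q) - 33L
    -10 * log10(mean(10^(-ph / 10)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write a read table back to FASTQ
#' @param reads Read table with `id`, `seq`, `qual`.
#' @param path Output FASTQ path (gzip if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual)))
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path)))
  invisible(path)
}

#' Quality/length read gate
#'
#' Retains reads whose mean quality strictly exceeds `q_min` and whose
#' length lies in `[len_min, len_max]` (inclusive). Defaults are the
#' long-range amplicon gates: quality > 9 and 8,000-16,000 nt, which keep
#' full-length and deletion-form product reads while discarding short
#' fragments and concatemers. Order is preserved and the filter is
#' idempotent.
#'
#' @param reads Read table from [read_fastq()].
#' @param q_min Minimum mean quality (strict).
#' @param len_min,len_max Inclusive length bounds (bp).
#' @return The retained rows of `reads`.
#' @export
filter_reads <- function(reads, q_min = 9, len_min = 8000L,
                         len_max = 16000L) {
  stopifnot(all(c("length_bp", "mean_q") %in% names(reads)))
  keep <- reads$mean_q > q_min &
    reads$length_bp >= len_min & reads$length_bp <= len_max
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define a structural form of an amplicon
#'
#' A structural form is one of the discrete reference sequences a read can
#' represent: typically the full-length product and a deletion-bearing
#' product. Reads are binned into forms by length ([classify_length()])
#' and genotyped against the form they align to best.
#'
#' @param label Form name, e.g. `"normal"` or `"deleted"`.
#' @param ref_seq Reference sequence of this form.
#' @param tolerance_bp Half-width of the length window used for binning.
#'   The default 300 bp leaves headroom for long-read indel noise while
#'   keeping forms separated by a multi-kb deletion unambiguous.
#' @param del_interval For a deletion form: the deleted interval in
#'   full-length-form coordinates (0-based half-open), used to mark sites
#'   inside the deletion as absent during genotyping.
#' @return An object of class `structural_form`.
#' @export
structural_form <- function(label, ref_seq, tolerance_bp = 300L,
                            del_interval = NULL) {
  ref_seq <- toupper(as.character(ref_seq))
  if (tolerance_bp <= 0L) stop("tolerance_bp must be positive")
  if (!is.null(del_interval)) del_interval <- as_interval(del_interval)
  structure(list(label = as.character(label), ref_seq = ref_seq,
                 expected_len_bp = nchar(ref_seq),
                 tolerance_bp = as.integer(tolerance_bp),
                 del_interval = del_interval),
            class = "structural_form")
}

#' Load structural forms from a FASTA file
#'
#' The longest record is taken as the full-length form; any shorter record
#' whose length equals full length minus the candidate deletion width gets
#' the deletion interval attached.
#'
#' @param path FASTA with one record per form; record names are the labels.
#' @param del_interval Optional candidate deletion (full-form coordinates,
#'   0-based half-open) attached to the matching shorter form.
#' @param tolerance_bp Length-window half-width for all forms.
#' @return Named list of `structural_form` objects.
#' @export
read_forms_fasta <- function(path, del_interval = NULL,
                             tolerance_bp = 300L) {
  fa <- Biostrings::readDNAStringSet(path)
  if (length(fa) == 0L) stop("no sequences in ", path)
  labels <- sub("\\s.*$", "", names(fa))
  lens <- Biostrings::width(fa)
  full_len <- max(lens)
  forms <- lapply(seq_along(fa), function(i) {
    di <- NULL
    if (!is.null(del_interval)) {
      del <- as_interval(del_interval)
      if (lens[i] == full_len - interval_width(del)) di <- del
    }
    structural_form(labels[i], as.character(fa[[i]]),
                    tolerance_bp = tolerance_bp, del_interval = di)
  })
  setNames(forms, labels)
}

# internal: min Hamming mismatches of `pattern` within `window` of either
# end of `subject` (both character); returns Inf when no hit <= max_mm
anchor_best_hit <- function(pattern, subject, window, max_mm) {
  p <- Biostrings::DNAString(pattern)
  s <- Biostrings::DNAString(subject)
  hits <- Biostrings::matchPattern(p, s, max.mismatch = max_mm,
                                   with.indels = FALSE)
  if (length(hits) == 0L) return(Inf)
  st <- IRanges::start(hits); en <- IRanges::end(hits)
  near_end <- st <= window | en >= length(s) - window + 1L
  if (!any(near_end)) return(Inf)
  mm <- Biostrings::neditStartingAt(p, s, starting.at = st[near_end],
                                    with.indels = FALSE)
  min(mm)
}

#' Assign reads to amplicons by anchor sequences
#'
#' A read is assigned to an amplicon when that amplicon's anchor (or its
#' reverse complement) occurs with at most `max_anchor_mismatches`
#' (Hamming, no indels) within `anchor_end_window_bp` of either read end.
#' If several amplicons match, the fewest-mismatch one wins; ties leave
#' the read unassigned with the `ambiguous` flag set. A read whose anchor
#' occurs only mid-read is not assigned, which is what separates an
#' amplicon with an end-proximal anchor from an overlapping amplicon that
#' contains the same sequence internally.
#'
#' @param reads Read table (columns `id`, `seq`).
#' @param scheme `amplicon_scheme` whose amplicons carry anchors.
#' @param max_anchor_mismatches Maximum Hamming mismatches (default 2).
#' @return `reads` with columns `amplicon_id` (NA when unassigned),
#'   `orientation` (`forward`/`reverse`/`unknown`), `ambiguous`.
#' @export
assign_amplicon <- function(reads, scheme, max_anchor_mismatches = 2L) {
  amps <- Filter(function(a) !is.null(a$anchor_seq), scheme$amplicons)
  if (length(amps) == 0L) stop("no amplicon in the scheme has an anchor")
  anchors <- lapply(amps, function(a) list(
    id = a$id, fwd = a$anchor_seq,
    rev = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(a$anchor_seq))),
    window = a$anchor_end_window_bp))

  n <- nrow(reads)
  amplicon_id <- rep(NA_character_, n)
  orientation <- rep("unknown", n)
  ambiguous <- rep(FALSE, n)

  for (i in seq_len(n)) {
    s <- reads$seq[i]
    best_mm <- Inf; best_id <- NA_character_; best_or <- "unknown"
    tie <- FALSE
    for (an in anchors) {
      mm_f <- anchor_best_hit(an$fwd, s, an$window, max_anchor_mismatches)
      mm_r <- anchor_best_hit(an$rev, s, an$window, max_anchor_mismatches)
      mm <- min(mm_f, mm_r)
      if (!is.finite(mm)) next
      orient <- if (mm_f < mm_r) "forward"
                else if (mm_r < mm_f) "reverse" else "unknown"
      if (mm < best_mm) {
        best_mm <- mm; best_id <- an$id; best_or <- orient; tie <- FALSE
      } else if (mm == best_mm && !identical(an$id, best_id)) {
        tie <- TRUE
      }
    }
    if (is.finite(best_mm) && !tie) {
      amplicon_id[i] <- best_id
      orientation[i] <- best_or
    } else if (tie) {
      ambiguous[i] <- TRUE
    }
  }
  reads$amplicon_id <- amplicon_id
  reads$orientation <- orientation
  reads$ambiguous <- ambiguous
  reads
}

#' Bin reads into structural forms by length
#'
#' Labels each read with the unique form whose expected length window
#' `expected_len_bp +/- tolerance_bp` contains the read length;
#' `NA` (unclassified) otherwise. Form windows must not overlap:
#' expected lengths must be separated by more than the sum of the two
#' tolerances.
#'
#' @param reads Read table with `length_bp`.
#' @param forms List of `structural_form` objects.
#' @return `reads` with a `form_label` column (NA = unclassified).
#' @export
classify_length <- function(reads, forms) {
  if (length(forms) == 0L) stop("forms must be non-empty")
  exp_len <- vapply(forms, `[[`, integer(1), "expected_len_bp")
  tol <- vapply(forms, `[[`, integer(1), "tolerance_bp")
  labels <- vapply(forms, `[[`, character(1), "label")
  if (length(forms) > 1L) {
    for (i in 1:(length(forms) - 1L)) for (j in (i + 1L):length(forms)) {
      if (abs(exp_len[i] - exp_len[j]) <= tol[i] + tol[j])
        stop("overlapping form windows: ", labels[i], " and ", labels[j])
    }
  }
  form_label <- rep(NA_character_, nrow(reads))
  for (k in seq_along(forms)) {
    inwin <- abs(reads$length_bp - exp_len[k]) <= tol[k]
    form_label[inwin] <- labels[k]
  }
  reads$form_label <- form_label
  reads
}

#' Write the per-read assignment table as TSV
#' @param reads Read table after assignment/classification.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_read_table <- function(reads, path) {
  cols <- intersect(c("id", "amplicon_id", "orientation", "length_bp",
                      "mean_q", "form_label", "haplotype"), names(reads))
  utils::write.table(reads[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
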