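#' Align one read to candidate structural forms
#'
#' Picks the form with the lowest normalized edit distance under a banded
#' global alignment with unit costs. The band is centred on the diagonal
#' shifted by the length difference and is generous relative to the indel
#' noise the package simulates and gates for, so within it the alignment
#' is optimal, not heuristic. Forms whose length difference alone already
#' exceeds the best distance found are skipped by exact dominance
#' (edit distance is bounded below by the length difference), never by a
#' heuristic guess.
#'
#' The returned `refmap` gives, for every form position, the 1-based read
#' position aligned to it (NA where the form base is absent from the
#' read), which is what per-site genotyping consumes.
#'
#' @param seq Read sequence (character).
#' @param forms List of `structural_form` objects.
#' @param max_norm_dist Unalignable threshold on distance divided by the
#'   longer of read and form length (default 0.25).
#' @param band_pad Extra band half-width beyond the length difference
#'   (default `max(150, 2%%` of form length)).
#' @return List with `form_label` (NA if unalignable), `dist`,
#'   `norm_dist`, `refmap`.
#' @export
align_to_forms <- function(seq, forms, max_norm_dist = 0.25,
                           band_pad = NULL) {
  seq <- toupper(seq)
  lr <- nchar(seq)
  lens <- vapply(forms, `[[`, integer(1), "expected_len_bp")
  # lower bound on normalized distance: |length difference| / max length
  lb <- abs(lr - lens) / pmax(lr, lens)
  ord <- order(lb)
  best <- list(form_label = NA_character_, dist = NA_integer_,
               norm_dist = Inf, refmap = NULL)
  for (k in ord) {
    if (lb[k] >= min(best$norm_dist, max_norm_dist)) break
    form <- forms[[k]]
    pad <- if (is.null(band_pad))
      max(150L, ceiling(0.02 * form$expected_len_bp)) else band_pad
    band <- as.integer(pad)
    res <- .banded_align_cpp(form$ref_seq, seq, band)
    if (is.na(res$dist)) next
    nd <- res$dist / max(lr, form$expected_len_bp)
    if (nd < best$norm_dist) {
      best <- list(form_label = form$label, dist = res$dist,
                   norm_dist = nd, refmap = res$refmap)
    }
  }
  if (best$norm_dist > max_norm_dist)
    return(list(form_label = NA_character_, dist = best$dist,
                norm_dist = best$norm_dist, refmap = NULL))
  best
}

#' Align a read table to structural forms
#'
#' @param reads Read table (columns `id`, `seq`).
#' @param forms List of `structural_form`s.
#' @param ... Passed to [align_to_forms()].
#' @return Named list (by read id) of [align_to_forms()] results.
#' @export
align_reads_to_forms <- function(reads, forms, ...) {
  out <- lapply(seq_len(nrow(reads)),
                function(i) align_to_forms(reads$seq[i], forms, ...))
  setNames(out, reads$id)
}
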