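#' Genomic interval (0-based, half-open)
#'
#' All internal coordinates in slipscan are 0-based half-open, the BED
#' convention; conversion to/from 1-based inclusive HGVS coordinates happens
#' only at input/output boundaries (see [hgvs_del_length()]).
#'
#' @param contig Contig / amplicon name (non-empty string).
#' @param start,end Integer bounds, `0 <= start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(contig, start, end, strand = ".") {
  if (!is.character(contig) || length(contig) != 1L || !nzchar(contig))
    stop("contig must be a non-empty string")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end")
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.'")
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s) [0-based half-open, width %d]\n",
              x$contig, x$start, x$end, x$strand, interval_width(x)))
  invisible(x)
}

#' Width of a genomic interval
#' @param x A `genomic_interval`.
#' @return Integer width in bp.
#' @export
interval_width <- function(x) x$end - x$start

# internal: coerce c(start, end) / list to genomic_interval on a contig
as_interval <- function(x, contig = "locus") {
  if (inherits(x, "genomic_interval")) return(x)
  if (is.numeric(x) && length(x) == 2L)
    return(genomic_interval(contig, x[[1L]], x[[2L]]))
  stop("cannot interpret interval; give a genomic_interval or c(start, end)")
}
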