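#' Length of an HGVS genomic range deletion
#'
#' Parses `g.<start>_<end>del` (an optional `accession:` prefix is
#' allowed) and returns the deleted length in bp under HGVS 1-based
#' inclusive coordinates: `end - start + 1`.
#'
#' @param hgvs_g HGVS genomic deletion string, e.g.
#'   `"NC_000012.12:g.6087520_6090118del"`.
#' @return Integer deletion length in bp.
#' @export
#' @examples
#' hgvs_del_length("g.6087520_6090118del")  # 2599
hgvs_del_length <- function(hgvs_g) {
  m <- regmatches(hgvs_g,
                  regexec("^(?:[A-Za-z0-9_.]+:)?g\\.([0-9]+)_([0-9]+)del$",
                          hgvs_g))[[1L]]
  if (length(m) != 3L)
    stop("cannot parse '", hgvs_g, "' as g.<start>_<end>del")
  start <- as.numeric(m[2L]); end <- as.numeric(m[3L])
  if (start > end) stop("parse error: start > end in '", hgvs_g, "'")
  as.integer(end - start + 1)
}

# single-letter -> three-letter amino acid codes (HGVS style)
AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Ter")

#' Coding consequence of a single-base substitution
#'
#' Locates the codon containing CDS position `c_pos`, substitutes the
#' alternate base, and translates both codons with the standard genetic
#' code.
#'
#' @param c_pos 1-based CDS position.
#' @param ref_base,alt_base Reference and alternate bases; `ref_base`
#'   must match the CDS.
#' @param cds_seq CDS sequence (first base = c.1).
#' @return List with `codon_index` (1-based), `aa_ref`, `aa_alt`
#'   (three-letter codes), `class` (`missense`, `synonymous`,
#'   `nonsense`).
#' @export
#' @examples
#' cds <- paste0(strrep("GCT", 2441), "CAG", "TAA")
#' coding_consequence(7326, "G", "T", cds)  # codon 2442, Gln -> His
coding_consequence <- function(c_pos, ref_base, alt_base, cds_seq) {
  cds_seq <- toupper(as.character(cds_seq))
  c_pos <- as.integer(c_pos)
  if (c_pos < 1L || c_pos > nchar(cds_seq))
    stop("c_pos outside CDS")
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  have <- substring(cds_seq, c_pos, c_pos)
  if (have != ref_base)
    stop("reference mismatch at c.", c_pos, ": CDS has ", have,
         ", expected ", ref_base)
  codon_index <- ceiling(c_pos / 3)
  cstart <- 3L * (codon_index - 1L) + 1L
  codon_ref <- substring(cds_seq, cstart, cstart + 2L)
  offset <- c_pos - cstart + 1L
  codon_alt <- codon_ref
  substring(codon_alt, offset, offset) <- alt_base
  aa1_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
  aa1_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  cls <- if (aa1_ref == aa1_alt) "synonymous"
         else if (aa1_alt == "*") "nonsense" else "missense"
  list(codon_index = codon_index,
       aa_ref = unname(AA_THREE[aa1_ref]),
       aa_alt = unname(AA_THREE[aa1_alt]),
       class = cls)
}

#' Toy transcript model for coordinate arithmetic
#'
#' Exons are supplied in transcript order (for a minus-strand transcript,
#' decreasing genomic coordinates) as 0-based half-open genomic
#' intervals. CDS positions are transcript positions minus the 5' UTR
#' length; the CDS length must be a multiple of 3.
#'
#' @param exons Data frame with `start`, `end` (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @param utr5,utr3 UTR lengths in transcript bases (defaults 0).
#' @param contig Contig name.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(exons, strand = "+", utr5 = 0L, utr3 = 0L,
                             contig = "chr") {
  stopifnot(all(c("start", "end") %in% names(exons)))
  if (any(exons$start >= exons$end)) stop("invalid exon intervals")
  gen_order <- order(exons$start)
  if (any(exons$end[gen_order][-nrow(exons)] >
          exons$start[gen_order][-1L]))
    stop("exons overlap")
  tx_order_ok <- if (strand == "+")
    !is.unsorted(exons$start, strictly = TRUE)
  else !is.unsorted(rev(exons$start), strictly = TRUE)
  if (!tx_order_ok)
    stop("exons must be given in transcript order for strand ", strand)
  widths <- exons$end - exons$start
  tx_len <- sum(widths)
  if ((tx_len - utr5 - utr3) %% 3L != 0L)
    stop("CDS length (transcript minus UTRs) must be divisible by 3")
  structure(list(exons = exons, strand = strand,
                 utr5 = as.integer(utr5), utr3 = as.integer(utr3),
                 widths = widths,
                 cum = cumsum(c(0L, widths[-length(widths)])),
                 tx_len = tx_len, contig = contig),
            class = "transcript_model")
}

#' Genomic to coding coordinate
#'
#' Maps a 1-based genomic position onto a transcript. Exonic positions
#' return a CDS coordinate (`offset = 0`); intronic positions return the
#' nearest exon-edge CDS coordinate with a `+`/`-` offset per HGVS
#' convention (the 5' half of an intron is `+` off the upstream exon's
#' last base, the 3' half `-` off the downstream exon's first base; the
#' middle base goes to `+`).
#'
#' @param g_pos 1-based genomic position.
#' @param tx A `transcript_model`.
#' @return List with `c_pos`, `offset` (0 for exonic), and `text`
#'   (e.g. `"657+5342"`).
#' @export
g_to_c <- function(g_pos, tx) {
  ex <- tx$exons
  n <- nrow(ex)
  span_lo <- min(ex$start) + 1L; span_hi <- max(ex$end)
  if (g_pos < span_lo || g_pos > span_hi)
    stop("g_pos ", g_pos, " outside transcript span")
  tpos_of <- function(i, g) {
    within <- if (tx$strand == "+") g - ex$start[i]
              else ex$end[i] - g + 1L
    tx$cum[i] + within
  }
  for (i in seq_len(n)) {
    if (g_pos >= ex$start[i] + 1L && g_pos <= ex$end[i]) {
      cpos <- tpos_of(i, g_pos) - tx$utr5
      return(list(c_pos = cpos, offset = 0L, text = as.character(cpos)))
    }
  }
  # intronic: find flanking exons in transcript order
  for (i in seq_len(n - 1L)) {
    up <- ex[i, ]; dn <- ex[i + 1L, ]
    in_intron <- if (tx$strand == "+")
      g_pos > up$end && g_pos <= dn$start
    else g_pos <= up$start && g_pos > dn$end
    if (!in_intron) next
    dist_up <- if (tx$strand == "+") g_pos - up$end
               else up$start - g_pos + 1L
    dist_dn <- if (tx$strand == "+") dn$start + 1L - g_pos
               else g_pos - dn$end
    if (dist_up <= dist_dn) {
      cpos <- tpos_of(i, if (tx$strand == "+") up$end else up$start + 1L) -
        tx$utr5
      return(list(c_pos = cpos, offset = dist_up,
                  text = sprintf("%d+%d", cpos, dist_up)))
    }
    cpos <- tpos_of(i + 1L, if (tx$strand == "+") dn$start + 1L
                            else dn$end) - tx$utr5
    return(list(c_pos = cpos, offset = -dist_dn,
                text = sprintf("%d-%d", cpos, dist_dn)))
  }
  stop("g_pos ", g_pos, " not located (outside exons and introns)")
}

#' Coding to genomic coordinate (inverse of [g_to_c()])
#'
#' @param c_pos 1-based CDS position.
#' @param tx A `transcript_model`.
#' @param offset Intronic offset (0 for exonic positions).
#' @return 1-based genomic position.
#' @export
c_to_g <- function(c_pos, tx, offset = 0L) {
  tpos <- c_pos + tx$utr5
  if (tpos < 1L || tpos > tx$tx_len) stop("c_pos outside transcript")
  i <- which(tpos <= cumsum(tx$widths))[1L]
  within <- tpos - tx$cum[i]
  ex <- tx$exons[i, ]
  g <- if (tx$strand == "+") ex$start + within else ex$end - within + 1L
  if (offset == 0L) return(g)
  if (tx$strand == "+") g + offset else g - offset
}

#' Filter called variants to rare nonsynonymous candidates
#'
#' Retains variants with population allele frequency strictly below
#' `af_threshold` whose consequence is neither synonymous nor
#' non-coding. Variants with no AF entry (absent from the local
#' frequency table) are retained and flagged `af_unverified`, mirroring
#' how a deletion absent from every population database is still a
#' candidate. Intronic variants (including intronic SVs) are retained
#' only when `include_intronic = TRUE`.
#'
#' @param variants Data frame with at least `consequence` and `af`
#'   columns; an optional `region_class` column
#'   (`exonic`/`intronic`/`flanking`) controls the intronic switch.
#' @param af_threshold Strict AF cutoff (default 0.01).
#' @param include_intronic Keep intronic candidates (default FALSE).
#' @return The candidate rows with an added logical `af_unverified`.
#' @export
filter_candidates <- function(variants, af_threshold = 0.01,
                              include_intronic = FALSE) {
  stopifnot(all(c("consequence", "af") %in% names(variants)))
  af <- variants$af
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stop("allele frequency outside [0, 1]")
  rare <- is.na(af) | af < af_threshold
  nonsyn <- !variants$consequence %in% c("synonymous", "non_coding")
  keep <- rare & nonsyn
  if ("region_class" %in% names(variants) && !include_intronic)
    keep <- keep & !(variants$region_class %in% "intronic")
  out <- variants[keep, , drop = FALSE]
  out$af_unverified <- is.na(out$af)
  rownames(out) <- NULL
  out
}

#' Read a local allele-frequency table
#'
#' The table stands in for a population frequency panel: TSV with either
#' a `key` column (`contig:pos:ref:alt`) or `contig`, `pos`, `ref`,
#' `alt` columns, plus `af`.
#'
#' @param path TSV path.
#' @return Data frame with `key` and `af`.
#' @export
read_af_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"af" %in% names(df)) stop("AF table needs an 'af' column")
  if (!"key" %in% names(df)) {
    need <- c("contig", "pos", "ref", "alt")
    if (!all(need %in% names(df)))
      stop("AF table needs 'key' or contig/pos/ref/alt columns")
    df$key <- paste(df$contig, df$pos, df$ref, df$alt, sep = ":")
  }
  df[, c("key", "af")]
}

#' Annotate variants with allele frequencies from a local table
#'
#' @param variants Data frame with `contig`, `pos`, `ref`, `alt`.
#' @param af_table Data frame from [read_af_table()].
#' @return `variants` with an `af` column (NA where not listed).
#' @export
annotate_af <- function(variants, af_table) {
  key <- paste(variants$contig, variants$pos, variants$ref,
               variants$alt, sep = ":")
  variants$af <- af_table$af[match(key, af_table$key)]
  variants
}

#' Read variant records from a VCF
#'
#' Uses vcfR; records become rows with `contig`, `pos` (1-based), `ref`,
#' `alt` and, when a single-sample GT field is present, `zygosity`
#' (`het`/`hom`).
#'
#' @param path VCF path.
#' @return Data frame of variant records.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  out <- data.frame(contig = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  gt <- tryCatch(vcfR::extract.gt(v), error = function(e) NULL)
  if (!is.null(gt) && ncol(gt) >= 1L) {
    g <- gsub("\\|", "/", gt[, 1L])
    out$zygosity <- ifelse(g %in% c("0/1", "1/0"), "het",
                           ifelse(g == "1/1", "hom", NA_character_))
  }
  out
}
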