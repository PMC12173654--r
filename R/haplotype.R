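#' Heterozygous SNV site table
#'
#' Het sites are given in full-length-form coordinates, 0-based.
#' `allele_a` and `allele_b` are the two phased alleles: all `allele_a`
#' bases belong to one haplotype (hapA) and all `allele_b` bases to the
#' other. The internal caller ([call_het_snvs()]) phases discovered sites
#' by read co-occurrence; externally supplied sites (VCF `GT 0|1` or TSV)
#' are taken as phased with REF = hapA.
#'
#' @param pos Integer vector of 0-based positions.
#' @param allele_a,allele_b Single-base alleles per site (must differ).
#' @return Data frame of class `het_sites`.
#' @export
het_sites <- function(pos, allele_a, allele_b) {
  pos <- as.integer(pos)
  allele_a <- toupper(allele_a); allele_b <- toupper(allele_b)
  if (any(allele_a == allele_b)) stop("allele_a and allele_b must differ")
  if (any(!c(allele_a, allele_b) %in% c("A", "C", "G", "T")))
    stop("alleles must be single bases A/C/G/T")
  df <- data.frame(pos = pos, allele_a = allele_a, allele_b = allele_b,
                   stringsAsFactors = FALSE)
  df <- df[order(df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("het_sites", class(df))
  df
}

#' Read het sites from TSV or VCF
#'
#' TSV needs columns `pos` (0-based), `allele_a`, `allele_b`. A VCF is
#' read with vcfR; biallelic SNV records are used, POS converted from
#' 1-based to 0-based, REF as `allele_a`, ALT as `allele_b`.
#'
#' @param path TSV or VCF file.
#' @return A `het_sites` data frame.
#' @export
read_het_sites <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
    keep <- nchar(ref) == 1L & nchar(alt) == 1L
    return(het_sites(as.integer(fix[keep, "POS"]) - 1L,
                     ref[keep], alt[keep]))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pos", "allele_a", "allele_b") %in% names(df)))
    stop("het site TSV needs columns pos, allele_a, allele_b")
  het_sites(df$pos, df$allele_a, df$allele_b)
}

#' Write het sites to TSV
#' @param sites A `het_sites` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_het_sites <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# internal: map a full-form 0-based position to a coordinate on `form`
# (0-based), or NA when the position falls inside the form's deletion
pos_on_form <- function(pos, form) {
  di <- form$del_interval
  if (is.null(di)) return(pos)
  out <- pos
  out[pos >= di$start & pos < di$end] <- NA_integer_
  shift <- pos >= di$end
  out[shift] <- pos[shift] - interval_width(di)
  out
}

#' Genotype one read at heterozygous SNV sites
#'
#' Reports, per site, whether the read carries the hapA allele (`A`), the
#' hapB allele (`B`), some other base (`other`, typically a sequencing
#' error), or no base at all (`absent`: the site lies inside the form's
#' deleted interval, or the alignment deletes the site's column).
#'
#' @param seq Read sequence.
#' @param alignment Result of [align_to_forms()] for this read.
#' @param form The `structural_form` the read aligned to.
#' @param sites A `het_sites` table (full-length-form coordinates).
#' @return Character vector of calls in `{A, B, other, absent}`, named by
#'   site position.
#' @export
genotype_read <- function(seq, alignment, form, sites) {
  calls <- rep("absent", nrow(sites))
  names(calls) <- sites$pos
  fpos <- pos_on_form(sites$pos, form)
  ok <- !is.na(fpos)
  if (any(ok)) {
    readpos <- alignment$refmap[fpos[ok] + 1L]
    base <- rep(NA_character_, sum(ok))
    has <- !is.na(readpos)
    base[has] <- substring(seq, readpos[has], readpos[has])
    call <- ifelse(is.na(base), "absent",
                   ifelse(base == sites$allele_a[ok], "A",
                          ifelse(base == sites$allele_b[ok], "B", "other")))
    calls[ok] <- call
  }
  calls
}

#' Genotype many reads and return the read x site call matrix
#'
#' @param reads Read table with `id`, `seq`, `form_label`.
#' @param alignments Named list from [align_reads_to_forms()].
#' @param forms Named list of `structural_form`s.
#' @param sites `het_sites` table.
#' @return Character matrix (rows = reads, columns = site positions).
#' @export
genotype_reads <- function(reads, alignments, forms, sites) {
  mat <- matrix("absent", nrow = nrow(reads), ncol = nrow(sites),
                dimnames = list(reads$id, sites$pos))
  for (i in seq_len(nrow(reads))) {
    al <- alignments[[reads$id[i]]]
    if (is.null(al) || is.na(al$form_label)) next
    mat[i, ] <- genotype_read(reads$seq[i], al, forms[[al$form_label]],
                              sites)
  }
  mat
}

#' Assign a haplotype to one genotyped read
#'
#' Majority vote over the read's informative calls (sites called `A` or
#' `B`). The read is `ambiguous` when it has fewer than `min_informative`
#' informative sites, when the vote ties, or when the minority fraction
#' exceeds `max_conflict_frac` (a cross-haplotype conflict rate that high
#' suggests a chimeric or misassigned read rather than sequencing error).
#'
#' @param calls Character vector of per-site calls for one read.
#' @param min_informative Minimum informative sites (default 3).
#' @param max_conflict_frac Maximum tolerated minority fraction
#'   (default 0.2; strictly greater is ambiguous).
#' @return `"hapA"`, `"hapB"` or `"ambiguous"`.
#' @export
assign_haplotype <- function(calls, min_informative = 3L,
                             max_conflict_frac = 0.2) {
  na <- sum(calls == "A"); nb <- sum(calls == "B")
  n <- na + nb
  if (n < min_informative || na == nb) return("ambiguous")
  conflict <- min(na, nb) / n
  if (conflict > max_conflict_frac) return("ambiguous")
  if (na > nb) "hapA" else "hapB"
}

#' Haplotype every read in a genotype matrix
#' @param genotypes Matrix from [genotype_reads()].
#' @param ... Passed to [assign_haplotype()].
#' @return Character vector of haplotype labels named by read id.
#' @export
assign_haplotypes <- function(genotypes, ...) {
  apply(genotypes, 1L, assign_haplotype, ...)
}

#' Detect the three-allele haplotype incongruence of a PCR artifact
#'
#' A genuine heterozygous deletion partitions reads into exactly two
#' allele classes: full-length reads of one haplotype and deletion-form
#' reads of the other, with no heterozygous SNVs inside the deleted span.
#' A slipped-strand PCR artifact instead produces deletion-form reads that
#' carry the *same* haplotype as one of the full-length groups (three
#' allele classes in total), and the deletion interval typically still
#' contains called het SNVs. This function applies those two rules.
#'
#' @param read_table Data frame with `read_id` (or `id`), `form_label`,
#'   `haplotype` for classified reads.
#' @param candidate_del Candidate deletion interval on the full-length
#'   form, `genomic_interval` or `c(start, end)` (0-based half-open).
#' @param sites `het_sites` table used for genotyping (full-form
#'   coordinates); sites strictly inside the deletion count as evidence.
#' @param deleted_label Form label of the deletion form
#'   (default `"deleted"`).
#' @param min_reads_per_class Minimum reads required in every counted
#'   allele class (default 5); smaller classes make the verdict
#'   `indeterminate`.
#' @param min_class_frac Minimum fraction of classified reads for a
#'   (haplotype, form) group to count as an allele class (default 0.05).
#' @param artifact_frac Fraction of deletion-form reads that must share a
#'   full-length haplotype to call the artifact (default 0.9; tolerates a
#'   few chimeric or misassigned reads).
#' @return An `artifact_verdict`: list with `verdict` (`consistent`,
#'   `artifact_suspected`, `indeterminate`), `allele_class_count`,
#'   `classes` (count table), `n_het_inside_del`, `evidence` (character).
#' @export
detect_incongruence <- function(read_table, candidate_del, sites,
                                deleted_label = "deleted",
                                min_reads_per_class = 5L,
                                min_class_frac = 0.05,
                                artifact_frac = 0.9) {
  del <- as_interval(candidate_del)
  if (!"read_id" %in% names(read_table) && "id" %in% names(read_table))
    read_table$read_id <- read_table$id
  cls <- read_table[!is.na(read_table$form_label) &
                      read_table$haplotype %in% c("hapA", "hapB"), ,
                    drop = FALSE]
  if (!any(read_table$form_label %in% deleted_label, na.rm = TRUE))
    stop("no candidate to evaluate: no deletion-form reads")
  total <- nrow(cls)
  tab <- as.data.frame(table(haplotype = cls$haplotype,
                             form = cls$form_label),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[names(tab) == "Freq"] <- "n"
  classes <- tab[tab$n >= min_class_frac * total, , drop = FALSE]
  rownames(classes) <- NULL
  n_classes <- nrow(classes)

  # het SNVs strictly inside the deleted span (breakpoint bases excluded)
  inside <- sites$pos > del$start & sites$pos < (del$end - 1L)
  n_inside <- sum(inside)

  evidence <- character(0)
  small <- classes$n < min_reads_per_class
  del_cls <- cls[cls$form_label == deleted_label, , drop = FALSE]
  normal_haps <- unique(classes$haplotype[classes$form != deleted_label])
  shared_frac <- 0
  shared_hap <- NA_character_
  if (nrow(del_cls) > 0L && length(normal_haps) > 0L) {
    fr <- vapply(normal_haps,
                 function(h) mean(del_cls$haplotype == h), numeric(1))
    shared_frac <- max(fr)
    shared_hap <- normal_haps[which.max(fr)]
  }

  rule_share <- shared_frac >= artifact_frac
  rule_inside <- n_inside >= 1L

  if (rule_share)
    evidence <- c(evidence, sprintf(
      "%.0f%% of %d deletion-form reads carry haplotype %s, shared with a full-length class",
      100 * shared_frac, nrow(del_cls), shared_hap))
  if (rule_inside)
    evidence <- c(evidence, sprintf(
      "%d heterozygous SNV(s) lie strictly inside the candidate deletion",
      n_inside))

  # a shared haplotype with fewer than 3 classes and no interior het SNV
  # cannot separate artifact from missing data: stay indeterminate
  artifact_ok <- rule_inside || (rule_share && n_classes >= 3L)
  if (any(small)) {
    verdict <- "indeterminate"
    evidence <- c(evidence, sprintf(
      "allele class below min_reads_per_class (%d)", min_reads_per_class))
    if (artifact_ok) verdict <- "artifact_suspected"
  } else if (artifact_ok) {
    verdict <- "artifact_suspected"
  } else if (rule_share) {
    verdict <- "indeterminate"
  } else {
    two_clean <- n_classes == 2L &&
      sum(classes$form == deleted_label) == 1L &&
      length(unique(classes$haplotype)) == 2L
    verdict <- if (two_clean && n_inside == 0L) "consistent"
               else "indeterminate"
    if (verdict == "consistent")
      evidence <- c(evidence,
                    "deletion- and full-length reads partition into 2 haplotype-disjoint classes; no het SNV inside the deletion")
  }

  structure(list(verdict = verdict, allele_class_count = n_classes,
                 classes = classes, n_het_inside_del = n_inside,
                 shared_frac = shared_frac, shared_hap = shared_hap,
                 evidence = evidence),
            class = "artifact_verdict")
}

#' @export
print.artifact_verdict <- function(x, ...) {
  cat(sprintf("verdict: %s (%d allele classes)\n", x$verdict,
              x$allele_class_count))
  print.data.frame(x$classes)
  for (e in x$evidence) cat(" -", e, "\n")
  invisible(x)
}

#' Orientation-balanced read subsampling
#'
#' Draws up to `n_per_orientation` reads from each orientation,
#' deterministically under the given seed. When an orientation has fewer
#' reads than requested, all of them are taken with a warning.
#'
#' @param reads Read table with an `orientation` column.
#' @param n_per_orientation Reads to draw per orientation (default 25).
#' @param seed Integer seed.
#' @return Subsampled read table.
#' @export
sample_reads <- function(reads, n_per_orientation = 25L, seed = 1L) {
  pick <- withr::with_seed(seed, {
    unlist(lapply(c("forward", "reverse"), function(o) {
      idx <- which(reads$orientation == o)
      if (length(idx) < n_per_orientation) {
        warning(sprintf("only %d %s reads available (requested %d)",
                        length(idx), o, n_per_orientation))
        idx
      } else {
        sort(sample(idx, n_per_orientation))
      }
    }))
  })
  out <- reads[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call heterozygous SNVs from aligned reads (internal caller)
#'
#' A deliberately simple pileup caller used when no external variant
#' calls are supplied: a site is heterozygous when its depth is at least
#' `min_depth` and the second-most-common base has frequency within
#' `[ab_low, ab_high]`. Discovered sites are phased against the deepest
#' site by read co-occurrence, so that `allele_a` across sites belongs to
#' one haplotype.
#'
#' @param basemat Character matrix of read bases in full-length-form
#'   coordinates (rows = reads, NA where a read has no base), from
#'   [build_base_matrix()].
#' @param min_depth Minimum depth (default 20).
#' @param ab_low,ab_high Allele-balance window for the second allele
#'   (defaults 0.2 and 0.8).
#' @return A `het_sites` data frame with extra columns `depth` and `ab`.
#' @export
call_het_snvs <- function(basemat, min_depth = 20L, ab_low = 0.2,
                          ab_high = 0.8) {
  if (is.null(basemat) || ncol(basemat) == 0L)
    return(het_sites(integer(0), character(0), character(0)))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b)
    colSums(basemat == b, na.rm = TRUE), numeric(ncol(basemat)))
  depth <- rowSums(counts)
  ord1 <- max.col(counts, ties.method = "first")
  top1 <- bases[ord1]
  counts2 <- counts
  counts2[cbind(seq_len(nrow(counts2)), ord1)] <- -1
  ord2 <- max.col(counts2, ties.method = "first")
  top2 <- bases[ord2]
  c2 <- counts2[cbind(seq_len(nrow(counts2)), ord2)]
  ab <- ifelse(depth > 0, c2 / depth, 0)
  is_het <- depth >= min_depth & ab >= ab_low & ab <= ab_high
  idx <- which(is_het)
  if (length(idx) == 0L)
    return(het_sites(integer(0), character(0), character(0)))

  # phase by co-occurrence with the deepest het site
  refsite <- idx[which.max(depth[idx])]
  lab <- function(j) {
    x <- basemat[, j]
    out <- rep(NA_character_, length(x))
    out[!is.na(x) & x == top1[j]] <- "a"
    out[!is.na(x) & x == top2[j]] <- "b"
    out
  }
  ref_lab <- lab(refsite)
  a1 <- top1[idx]; a2 <- top2[idx]
  for (k in seq_along(idx)) {
    j <- idx[k]
    if (j == refsite) next
    lj <- lab(j)
    both <- !is.na(ref_lab) & !is.na(lj)
    if (!any(both)) next
    same <- sum(ref_lab[both] == lj[both])
    if (same < sum(both) - same) {  # discordant majority: swap alleles
      tmp <- a1[k]; a1[k] <- a2[k]; a2[k] <- tmp
    }
  }
  pos <- as.integer(colnames(basemat)[idx])
  out <- het_sites(pos, a1, a2)
  o <- order(pos)
  out$depth <- depth[idx][o]
  out$ab <- ab[idx][o]
  out
}

#' Project aligned reads onto full-length-form coordinates
#'
#' Builds the read x position base matrix that [call_het_snvs()] piles
#' up. Full-length-form reads contribute everywhere their alignment has a
#' base; deletion-form reads contribute only outside the deleted span.
#'
#' @param reads Read table with `id`, `seq`.
#' @param alignments Named list from [align_reads_to_forms()].
#' @param forms Named list of `structural_form`s.
#' @param full_len Length of the full-length form.
#' @return Character matrix with one column per full-form position
#'   (0-based position labels), NA where a read has no aligned base.
#' @export
build_base_matrix <- function(reads, alignments, forms, full_len) {
  mat <- matrix(NA_character_, nrow = nrow(reads), ncol = full_len,
                dimnames = list(reads$id, 0:(full_len - 1L)))
  for (i in seq_len(nrow(reads))) {
    al <- alignments[[reads$id[i]]]
    if (is.null(al) || is.na(al$form_label)) next
    form <- forms[[al$form_label]]
    di <- form$del_interval
    # full-form positions this form covers
    if (is.null(di)) {
      fullpos <- seq_len(full_len)            # 1-based
      formpos <- fullpos
    } else {
      w <- interval_width(di)
      fullpos <- c(seq_len(di$start),
                   if (di$end < full_len) (di$end + 1L):full_len)
      formpos <- c(seq_len(di$start),
                   if (di$end < full_len) (di$start + 1L):(full_len - w))
    }
    rp <- al$refmap[formpos]
    has <- !is.na(rp)
    bases <- strsplit(reads$seq[i], "", fixed = TRUE)[[1L]]
    mat[i, fullpos[has]] <- bases[rp[has]]
  }
  mat
}
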