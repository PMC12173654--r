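#' Run the full artifact check on one amplicon
#'
#' Orchestrates the screening workflow for a candidate deletion inside
#' one long-range PCR amplicon: read the FASTQ, apply the quality/length
#' gates, assign reads to the amplicon by anchor, bin them into
#' structural forms by length, align each read to its form, genotype
#' reads at heterozygous SNVs, group them into haplotypes, test for the
#' three-allele incongruence, and scan the deletion breakpoints for
#' direct repeats on the reference and on the suspect haplotype.
#'
#' @param fastq FASTQ path (reads of the amplicon of interest, possibly
#'   mixed with others).
#' @param forms_fasta FASTA with one record per structural form; the
#'   longest record is the full-length form.
#' @param candidate_del Candidate deletion on the full-length form:
#'   `c(start, end)` 0-based half-open, or a local HGVS string
#'   `"g.<start>_<end>del"` (1-based inclusive).
#' @param scheme Tiling scheme: `amplicon_scheme` or scheme TSV path.
#' @param het_sites_file Het sites (TSV or VCF) in full-length-form
#'   coordinates; `NULL` uses the internal pileup caller.
#' @param out_dir Optional directory for the report JSON and
#'   intermediate TSVs.
#' @param q_min,len_min,len_max Read gates (see [filter_reads()]).
#' @param max_anchor_mismatches Anchor matching tolerance.
#' @param tolerance_bp Form length-window half-width.
#' @param n_per_orientation If non-NULL, subsample this many reads per
#'   orientation ([sample_reads()]) before genotyping.
#' @param seed Seed for the optional subsampling.
#' @param flag_min_len Slippage-propensity repeat threshold.
#' @param ... Passed to [detect_incongruence()].
#' @return List of class `artifact_report`: `verdict`
#'   (`artifact_verdict`), `repeat_context`, `propensity`, `read_table`,
#'   `genotypes`, `sites`, `counts`, `config`.
#' @export
run_artifact_check <- function(fastq, forms_fasta, candidate_del, scheme,
                               het_sites_file = NULL, out_dir = NULL,
                               q_min = 9, len_min = 8000L,
                               len_max = 16000L,
                               max_anchor_mismatches = 2L,
                               tolerance_bp = 300L,
                               n_per_orientation = NULL, seed = 1L,
                               flag_min_len = 15L, ...) {
  if (is.character(scheme)) scheme <- read_scheme(scheme)
  del <- parse_candidate_del(candidate_del)
  forms <- read_forms_fasta(forms_fasta, del_interval = del,
                            tolerance_bp = tolerance_bp)
  full <- forms[[which.max(vapply(forms, `[[`, integer(1),
                                  "expected_len_bp"))]]
  deleted_label <- setdiff(vapply(forms, `[[`, character(1), "label"),
                           full$label)
  if (length(deleted_label) != 1L)
    stop("expected exactly two structural forms (full-length + deletion)")

  reads <- read_fastq(fastq)
  n_input <- nrow(reads)
  reads <- filter_reads(reads, q_min = q_min, len_min = len_min,
                        len_max = len_max)
  n_pass <- nrow(reads)
  reads <- assign_amplicon(reads, scheme,
                           max_anchor_mismatches = max_anchor_mismatches)
  reads <- reads[!is.na(reads$amplicon_id), , drop = FALSE]
  reads <- classify_length(reads, forms)
  reads <- reads[!is.na(reads$form_label), , drop = FALSE]
  if (!is.null(n_per_orientation))
    reads <- sample_reads(reads, n_per_orientation, seed = seed)

  # orient reads to the form strand before alignment and genotyping;
  # unknown-orientation reads are tried as-is (alignment will reject a
  # wrong-strand read rather than mis-genotype it)
  rc <- reads$orientation == "reverse"
  reads$seq[rc] <- vapply(reads$seq[rc], function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1), USE.NAMES = FALSE)

  alignments <- align_reads_to_forms(reads, forms)
  aligned <- !vapply(alignments, function(a) is.na(a$form_label),
                     logical(1))
  reads <- reads[aligned, , drop = FALSE]
  alignments <- alignments[reads$id]

  sites <- if (is.null(het_sites_file)) {
    call_het_snvs(build_base_matrix(reads, alignments, forms,
                                    full$expected_len_bp))
  } else {
    read_het_sites(het_sites_file)
  }
  if (nrow(sites) == 0L)
    stop("no heterozygous SNV sites available for haplotyping")

  genotypes <- genotype_reads(reads, alignments, forms, sites)
  reads$haplotype <- unname(assign_haplotypes(genotypes))

  verdict <- detect_incongruence(
    reads[, c("id", "form_label", "haplotype")], del, sites,
    deleted_label = deleted_label, ...)

  # rescan breakpoints on the haplotype the deletion-form reads carry
  suspect <- verdict$shared_hap
  if (is.na(suspect)) {
    del_reads <- reads$haplotype[reads$form_label == deleted_label]
    del_reads <- del_reads[del_reads %in% c("hapA", "hapB")]
    suspect <- if (length(del_reads)) names(which.max(table(del_reads)))
               else "hapB"
  }
  allele <- if (suspect == "hapA") sites$allele_a else sites$allele_b
  ref_base <- substring(full$ref_seq, sites$pos + 1L, sites$pos + 1L)
  hap_snvs <- data.frame(pos = sites$pos, ref = ref_base, alt = allele,
                         stringsAsFactors = FALSE)
  hap_snvs <- hap_snvs[hap_snvs$ref != hap_snvs$alt, , drop = FALSE]
  ctx <- apply_haplotype_and_rescan(full$ref_seq, hap_snvs, del)
  prop <- slippage_propensity(ctx, flag_min_len = flag_min_len)
  verdict$evidence <- c(verdict$evidence, prop$rationale)

  counts <- list(
    input = n_input, pass_filter = n_pass, assigned = nrow(reads),
    by_form = as.list(table(reads$form_label)),
    by_class = stats::setNames(
      as.list(verdict$classes$n),
      paste(verdict$classes$haplotype, verdict$classes$form, sep = "/")))

  report <- structure(list(
    verdict = verdict, repeat_context = ctx, propensity = prop,
    read_table = reads[, c("id", "amplicon_id", "orientation",
                           "length_bp", "mean_q", "form_label",
                           "haplotype")],
    genotypes = genotypes, sites = sites, counts = counts,
    config = list(q_min = q_min, len_min = len_min, len_max = len_max,
                  max_anchor_mismatches = max_anchor_mismatches,
                  tolerance_bp = tolerance_bp,
                  n_per_orientation = n_per_orientation, seed = seed,
                  flag_min_len = flag_min_len,
                  candidate_del = c(del$start, del$end),
                  version = as.character(utils::packageVersion("slipscan")))),
    class = "artifact_report")

  if (!is.null(out_dir)) write_artifact_report(report, out_dir)
  report
}

# internal: candidate deletion from c(start, end) or local HGVS g. string
parse_candidate_del <- function(x) {
  if (inherits(x, "genomic_interval")) return(x)
  if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec(
      "^(?:[A-Za-z0-9_.]+:)?g\\.([0-9]+)_([0-9]+)del$", x))[[1L]]
    if (length(m) != 3L) stop("cannot parse candidate deletion '", x, "'")
    # HGVS 1-based inclusive -> 0-based half-open
    return(genomic_interval("amplicon", as.integer(m[2L]) - 1L,
                            as.integer(m[3L])))
  }
  as_interval(x)
}

#' Write an artifact report to disk
#'
#' Emits `report.json` (verdict, repeat context, counts, resolved
#' config, package version), `read_table.tsv`, `genotypes.tsv` and
#' `het_sites.tsv`.
#'
#' @param report An `artifact_report`.
#' @param dir Output directory (created if needed).
#' @return Named list of paths, invisibly.
#' @export
write_artifact_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- report$verdict
  ctx <- report$repeat_context
  json <- list(
    verdict = v$verdict,
    allele_class_count = v$allele_class_count,
    classes = v$classes,
    n_het_inside_del = v$n_het_inside_del,
    evidence = v$evidence,
    repeat_context = list(
      del_start = ctx$del_interval$start, del_end = ctx$del_interval$end,
      repeat_len_ref = ctx$repeat_len_ref,
      repeat_len_hap = ctx$repeat_len_hap,
      repeat_seq_ref = ctx$repeat_seq_ref,
      repeat_seq_hap = ctx$repeat_seq_hap,
      spacer_len = ctx$spacer_len,
      n_snvs_applied = nrow(ctx$snvs_applied),
      propensity = report$propensity$level),
    counts = report$counts,
    config = report$config)
  paths <- list(report = file.path(dir, "report.json"),
                read_table = file.path(dir, "read_table.tsv"),
                genotypes = file.path(dir, "genotypes.tsv"),
                het_sites = file.path(dir, "het_sites.tsv"))
  jsonlite::write_json(json, paths$report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  write_read_table(report$read_table, paths$read_table)
  gt <- data.frame(read_id = rownames(report$genotypes),
                   report$genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(gt, paths$genotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_het_sites(report$sites, paths$het_sites)
  invisible(paths)
}

#' @export
print.artifact_report <- function(x, ...) {
  cat("== slipscan artifact check ==\n")
  cat(sprintf("reads: %d input, %d passed gates, %d assigned+classified\n",
              x$counts$input, x$counts$pass_filter, x$counts$assigned))
  print(x$verdict)
  print(x$repeat_context)
  cat(x$propensity$rationale, "\n")
  invisible(x)
}
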