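## Batch annotation and human-readable report rendering.

#' Render the decision trace of an assignment
#'
#' @param assignment a `subgroup_assignment`.
#' @return character scalar: the flowchart path taken, one step per line,
#'   ending in the rule/subgroup and its spliceogenicity annotation.
#' @export
render_trace <- function(assignment) {
  stopifnot(inherits(assignment, "subgroup_assignment"))
  lines <- assignment$trace
  if (length(lines) == 0L) {
    lines <- paste("no heuristic evaluated:",
                   paste(assignment$flags, collapse = ","))
  }
  if (!is.na(assignment$rule_id) && !is.null(assignment$annotation)) {
    a <- assignment$annotation
    lines <- c(lines, sprintf("spliceogenicity %.1f%% [%.1f-%.1f] (n=%d, %s)",
                              a$p, a$ci[1], a$ci[2], a$n, a$source))
  }
  if (length(assignment$flags)) {
    lines <- c(lines, paste("flags:", paste(assignment$flags, collapse = ",")))
  }
  paste(lines, collapse = "\n")
}

## One flat report row per (variant, assignment).
assignment_row <- function(v, tm, a) {
  ann <- a$annotation
  data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    transcript_id = tm$transcript_id,
    site_class = a$site_class %||% NA_character_,
    label = a$label, rule_id = a$rule_id,
    subgroup = a$subgroup,
    spliceogenicity = if (is.null(ann)) NA_real_ else ann$p,
    ci_low = if (is.null(ann)) NA_real_ else ann$ci[1],
    ci_high = if (is.null(ann)) NA_real_ else ann$ci[2],
    n = if (is.null(ann)) NA_integer_ else ann$n,
    flags = paste(a$flags, collapse = ","),
    trace = paste(a$trace, collapse = " | ")
  )
}

#' Annotate a VCF of variants against transcript models
#'
#' Every variant is classified against every supplied transcript on its
#' contig: SNVs through the DD/DA decision trees, indels through the
#' multi-position pathway. Variants outside the heuristic windows receive an
#' explicit flag (`deep_intronic` with a pseudoexon-scan hint, or
#' `SRE_not_covered` for exonic positions); U12-intron variants are flagged
#' unsupported. REF-mismatching records are warned about, flagged and kept.
#'
#' @param vcf_path input VCF.
#' @param transcripts list of [transcript_model()]s (or a GTF path).
#' @param genome genome (named character vector, `DNAStringSet`, FASTA path).
#' @param out_tsv,out_vcf optional output paths (TSV report; annotated VCF
#'   with `HEUR_*` INFO keys).
#' @param rule_table a [load_rule_table()] result.
#' @return list with `report` (data.frame), `n_warnings`, `paths`.
#' @export
run_annotate <- function(vcf_path, transcripts, genome, out_tsv = NULL,
                         out_vcf = NULL, rule_table = load_rule_table()) {
  if (is.character(transcripts) && length(transcripts) == 1L) {
    transcripts <- load_transcript_annotation(transcripts)
  }
  genome <- as_genome(genome)
  for (tm in transcripts) {
    if (!tm$chrom %in% names(genome)) {
      stop("contig ", tm$chrom, " absent from genome FASTA")
    }
  }
  vcf <- VariantAnnotation::readVcf(vcf_path)
  variants <- load_vcf(vcf_path, genome)
  n_warn <- 0L
  report <- NULL
  per_record <- character(length(variants))
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    if (isTRUE(attr(v, "ref_mismatch"))) {
      warning(sprintf("REF mismatch at %s:%d; record flagged", v$chrom, v$pos),
              call. = FALSE)
      n_warn <- n_warn + 1L
      report <- rbind(report, data.frame(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        transcript_id = NA, site_class = NA, label = NA, rule_id = NA,
        subgroup = NA, spliceogenicity = NA, ci_low = NA, ci_high = NA,
        n = NA, flags = "ref_mismatch", trace = ""))
      per_record[i] <- "ref_mismatch"
      next
    }
    hits <- character()
    for (tm in transcripts) {
      if (tm$chrom != v$chrom) next
      if (v$variant_class == "SNV") {
        a <- classify_snv(v, tm, genome, rule_table)
        as_list <- c(list(a), attr(a, "secondary"))
      } else {
        as_list <- list(classify_indel(v, tm, genome, rule_table)$summary)
      }
      for (a in as_list) {
        report <- rbind(report, assignment_row(v, tm, a))
        hits <- c(hits, if (!is.na(a$rule_id)) {
          sprintf("%s:%s:%.1f", a$rule_id, a$subgroup, a$annotation$p)
        } else if ("deep_intronic" %in% a$flags) {
          "deep_intronic:pseudoexon_scan_hint"
        } else {
          paste(a$flags, collapse = "&")
        })
      }
    }
    per_record[i] <- if (length(hits)) paste(hits, collapse = "|") else "no_transcript"
  }
  if (is.null(report)) {
    report <- assignment_row(variant_record("chr0", 1, "A", "C"),
                             list(transcript_id = NA), subgroup_assignment())[0, ]
  }
  paths <- character()
  if (!is.null(out_tsv)) {
    data.table::fwrite(report, out_tsv, sep = "\t")
    paths <- c(paths, out_tsv)
  }
  if (!is.null(out_vcf) && length(vcf) > 0L) {
    hdr <- VariantAnnotation::header(vcf)
    newinfo <- S4Vectors::DataFrame(
      Number = "1", Type = "String",
      Description = "Splicing heuristic assignment (rule:subgroup:spliceogenicity) or flag",
      row.names = "HEUR")
    VariantAnnotation::info(hdr) <- rbind(VariantAnnotation::info(hdr), newinfo)
    VariantAnnotation::header(vcf) <- hdr
    ## collapse per expanded allele back onto VCF records
    n_alt <- vapply(SummarizedExperiment::rowRanges(vcf)$ALT, length, integer(1))
    idx <- rep(seq_along(n_alt), n_alt)
    rec <- vapply(seq_along(n_alt), function(r)
      paste(per_record[idx == r], collapse = ","), character(1))
    VariantAnnotation::info(vcf)$HEUR <- rec
    VariantAnnotation::writeVcf(vcf, out_vcf)
    paths <- c(paths, out_vcf)
  }
  list(report = report, n_warnings = n_warn, paths = paths)
}
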