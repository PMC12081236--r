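#' Variant record
#'
#' A single small variant in VCF-style coordinates (1-based `pos`; `ref` and
#' `alt` written on the plus strand of the reference genome).
#'
#' @param chrom contig.
#' @param pos 1-based genomic position of the first `ref` base.
#' @param ref,alt reference / alternative alleles (plus strand).
#' @return object of class `variant_record` with a derived `variant_class`
#'   of `SNV`, `insertion`, `deletion` or `delins`.
#' @export
variant_record <- function(chrom, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) == 0L) stop("ref must be non-empty (use anchored VCF alleles)")
  if (!grepl("^[ACGTN]+$", ref) || !grepl("^[ACGTN]*$", alt)) {
    stop("alleles must be A/C/G/T/N")
  }
  cls <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
  else if (nchar(ref) < nchar(alt) && substr(alt, 1, nchar(ref)) == ref) "insertion"
  else if (nchar(ref) > nchar(alt) && (nchar(alt) == 0L || substr(ref, 1, nchar(alt)) == alt)) "deletion"
  else "delins"
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 variant_class = cls), class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant_record> %s:%d %s>%s (%s)\n", x$chrom, x$pos, x$ref,
              x$alt, x$variant_class))
  invisible(x)
}

#' Load variants from a VCF file
#'
#' Thin wrapper over [VariantAnnotation::readVcf()]. Multi-allelic records
#' are expanded to one [variant_record()] per ALT allele. When a genome is
#' supplied, each record's REF is checked against the reference sequence;
#' mismatching records are returned with a `ref_mismatch` flag.
#'
#' @param path VCF file.
#' @param genome optional genome (named character vector, `DNAStringSet` or
#'   FASTA path) for REF validation.
#' @return list of `variant_record`s; mismatching records carry
#'   `attr(x, "ref_mismatch") = TRUE`.
#' @export
load_vcf <- function(path, genome = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  if (length(vcf) == 0L) return(list())
  vr <- SummarizedExperiment::rowRanges(vcf)
  if (!is.null(genome)) genome <- as_genome(genome)
  out <- list()
  for (i in seq_along(vr)) {
    chrom <- as.character(GenomicRanges::seqnames(vr)[i])
    pos <- GenomicRanges::start(vr)[i]
    ref <- as.character(vr$REF[i])
    alts <- as.character(vr$ALT[[i]])
    for (alt in alts) {
      v <- variant_record(chrom, pos, ref, alt)
      if (!is.null(genome)) {
        sl <- genome_slice(genome, chrom, pos - 1L, pos - 1L + nchar(ref))
        if (!identical(sl$seq, ref)) attr(v, "ref_mismatch") <- TRUE
      }
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

## Sense-strand sequence for a transcript-oriented window given its genomic
## interval (0-based half-open). Clipped ends are padded with N and flagged.
sense_window <- function(genome, tm, gstart0, gend0) {
  sl <- genome_slice(genome, tm$chrom, gstart0, gend0)
  seq <- sl$seq
  if (sl$clipped_left) seq <- paste0(strrep("N", max(0L, -gstart0)), seq)
  if (sl$clipped_right) {
    seq <- paste0(seq, strrep("N", gend0 - nchar(genome[[tm$chrom]])))
  }
  sense <- if (tm$strand == "+") seq else revcomp(seq)
  list(gstart0 = gstart0, gend0 = gend0, seq_plus = seq, sense = sense,
       truncated = sl$clipped_left || sl$clipped_right)
}

#' Extract the splice context of an intron
#'
#' Sense-strand windows flanking both splice sites of one intron: the last
#' `exonic_n` nt of the upstream exon and first `intronic_n` nt of the intron
#' (donor side), and the last `acceptor_intronic_n` nt of the intron plus the
#' first `exonic_n` nt of the downstream exon (acceptor side). Windows
#' extending past a contig end are padded with `N` and flagged `truncated`;
#' an intron shorter than the two intronic windows yields overlapping windows
#' flagged `overlap`.
#'
#' @param tm a [transcript_model()].
#' @param intron_index intron number in transcript orientation.
#' @param genome genome (named character vector, `DNAStringSet`, FASTA path).
#' @param exonic_n,intronic_n,acceptor_intronic_n window sizes in nt
#'   (acceptor intronic window is configurable to 100 for branchpoint work).
#' @return object of class `splice_context` with sense-strand sequences
#'   `donor_exonic`, `donor_intronic`, `acceptor_intronic`, `acceptor_exonic`.
#' @export
extract_splice_context <- function(tm, intron_index, genome, exonic_n = 50L,
                                   intronic_n = 50L,
                                   acceptor_intronic_n = 50L) {
  genome <- as_genome(genome)
  ins <- introns(tm)
  stopifnot(intron_index >= 1L, intron_index <= nrow(ins))
  M <- ins$length[intron_index]
  up <- intron_index; dn <- intron_index + 1L
  up_len <- exon_length(tm, up); dn_len <- exon_length(tm, dn)
  ex_up_n <- min(exonic_n, up_len)
  ex_dn_n <- min(exonic_n, dn_len)
  plus <- tm$strand == "+"
  ## genomic intervals per window (0-based half-open)
  iv <- function(p_lo, p_hi) c(min(p_lo, p_hi) - 1L, max(p_lo, p_hi))
  d_ex <- iv(rel_to_genomic(tm, intron_index, "donor", paste0("E-", ex_up_n)),
             rel_to_genomic(tm, intron_index, "donor", "E-1"))
  d_in <- iv(rel_to_genomic(tm, intron_index, "donor", "+1"),
             rel_to_genomic(tm, intron_index, "donor", paste0("+", min(intronic_n, M))))
  a_in <- iv(rel_to_genomic(tm, intron_index, "acceptor",
                            paste0("-", min(acceptor_intronic_n, M))),
             rel_to_genomic(tm, intron_index, "acceptor", "-1"))
  a_ex <- iv(rel_to_genomic(tm, intron_index, "acceptor", "E+1"),
             rel_to_genomic(tm, intron_index, "acceptor", paste0("E+", ex_dn_n)))
  w <- list(donor_exonic = sense_window(genome, tm, d_ex[1], d_ex[2]),
            donor_intronic = sense_window(genome, tm, d_in[1], d_in[2]),
            acceptor_intronic = sense_window(genome, tm, a_in[1], a_in[2]),
            acceptor_exonic = sense_window(genome, tm, a_ex[1], a_ex[2]))
  structure(list(
    transcript_id = tm$transcript_id, chrom = tm$chrom, strand = tm$strand,
    intron_index = intron_index, intron_length = M,
    windows = w,
    donor_exonic = w$donor_exonic$sense,
    donor_intronic = w$donor_intronic$sense,
    acceptor_intronic = w$acceptor_intronic$sense,
    acceptor_exonic = w$acceptor_exonic$sense,
    flags = list(
      truncated = any(vapply(w, `[[`, logical(1), "truncated")),
      overlap = M < intronic_n + acceptor_intronic_n
    )
  ), class = "splice_context")
}

#' @export
print.splice_context <- function(x, ...) {
  cat(sprintf("<splice_context> %s intron %d (%d nt)%s\n", x$transcript_id,
              x$intron_index, x$intron_length,
              if (x$flags$overlap) " [windows overlap]" else ""))
  cat(" donor:    ", x$donor_exonic, "|", x$donor_intronic, "\n")
  cat(" acceptor: ", x$acceptor_intronic, "|", x$acceptor_exonic, "\n")
  invisible(x)
}

#' Apply a variant to a splice context
#'
#' Produces an edited copy of the context in which every window overlapping
#' the variant has the ALT allele spliced in (windows are re-oriented to the
#' transcript sense strand, so a minus-strand genomic C>A appears as G>T).
#' The reference context is retained in `$ref_context`, and the length
#' difference for indels is recorded in `$shift`.
#'
#' @param context a [extract_splice_context()] result.
#' @param variant a [variant_record()].
#' @return edited `splice_context` with `$ref_context` and `$shift`.
#' @export
apply_variant <- function(context, variant) {
  stopifnot(inherits(context, "splice_context"), inherits(variant, "variant_record"))
  if (variant$chrom != context$chrom) {
    stop("variant contig does not match context")
  }
  vs0 <- variant$pos - 1L                      # 0-based start of REF span
  ve0 <- vs0 + nchar(variant$ref)              # 0-based end (half-open)
  touched <- FALSE
  out <- context
  for (nm in names(context$windows)) {
    w <- context$windows[[nm]]
    if (ve0 <= w$gstart0 || vs0 >= w$gend0) next
    if (vs0 < w$gstart0 || ve0 > w$gend0) {
      stop("variant extends beyond context window ", nm)
    }
    off <- vs0 - w$gstart0                     # offset within plus-strand seq
    have <- substr(w$seq_plus, off + 1L, off + nchar(variant$ref))
    if (!identical(have, variant$ref)) {
      stop(sprintf("REF mismatch at %s:%d: expected '%s', context has '%s'",
                   variant$chrom, variant$pos, variant$ref, have))
    }
    w$seq_plus <- paste0(substr(w$seq_plus, 1L, off), variant$alt,
                         substr(w$seq_plus, off + nchar(variant$ref) + 1L,
                                nchar(w$seq_plus)))
    w$sense <- if (context$strand == "+") w$seq_plus else revcomp(w$seq_plus)
    out$windows[[nm]] <- w
    out[[nm]] <- w$sense
    touched <- TRUE
  }
  if (!touched) stop("variant does not overlap any context window")
  out$ref_context <- context
  out$shift <- nchar(variant$alt) - nchar(variant$ref)
  out
}
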