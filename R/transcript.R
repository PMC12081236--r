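#' Transcript model
#'
#' A strand-aware, ordered exon structure for one transcript. Exons are stored
#' 0-based half-open in genomic coordinates but ordered in transcript (5'->3')
#' orientation, so exon 1 is always the 5'-most exon of the mRNA; on the minus
#' strand that is the exon with the largest genomic coordinates. Intron `i`
#' lies between exons `i` and `i + 1` and carries a spliceosome class (`U2`,
#' `U12` or `unknown`); only U2 introns are covered by the disruption
#' heuristics.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors, 0-based half-open genomic
#'   coordinates (any order; sorted internally).
#' @param intron_classes optional character vector (length = exons - 1) of
#'   `"U2"`, `"U12"` or `"unknown"`; defaults to `"U2"`.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends, intron_classes = NULL) {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1L)
  if (!strand %in% c("+", "-")) stop("unknown strand: ", strand)
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (any(exon_ends <= exon_starts)) stop("empty exon interval")
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]; exon_ends <- exon_ends[o]
  n <- length(exon_starts)
  if (n > 1L && any(exon_starts[-1L] < exon_ends[-n])) {
    stop(sprintf("transcript %s: overlapping exons", transcript_id))
  }
  if (n > 1L && any(exon_starts[-1L] == exon_ends[-n])) {
    stop(sprintf("transcript %s: zero-length intron", transcript_id))
  }
  if (strand == "-") { # transcript orientation: reverse genomic order
    exon_starts <- rev(exon_starts); exon_ends <- rev(exon_ends)
  }
  if (is.null(intron_classes)) intron_classes <- rep("U2", max(0L, n - 1L))
  if (length(intron_classes) != n - 1L) {
    stop("intron_classes must have length exons - 1")
  }
  if (!all(intron_classes %in% c("U2", "U12", "unknown"))) {
    stop("intron classes must be U2/U12/unknown")
  }
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand,
    exons = data.frame(start = exon_starts, end = exon_ends),
    intron_classes = intron_classes
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s n_exons=%d\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, n_exons(x)))
  invisible(x)
}

#' @rdname transcript_model
#' @param tm a `transcript_model`.
#' @export
n_exons <- function(tm) nrow(tm$exons)

#' Intron intervals of a transcript
#'
#' @param tm a `transcript_model`.
#' @return data.frame with 0-based half-open genomic `start`/`end`, `length`
#'   and `class`, one row per intron in transcript orientation (may be empty).
#' @export
introns <- function(tm) {
  n <- n_exons(tm)
  if (n < 2L) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), class = character()))
  }
  if (tm$strand == "+") {
    s <- tm$exons$end[-n]; e <- tm$exons$start[-1L]
  } else {
    ## on '-' strand exon i+1 is genomically upstream (lower coords) of exon i
    s <- tm$exons$end[-1L]; e <- tm$exons$start[-n]
  }
  data.frame(start = s, end = e, length = e - s, class = tm$intron_classes)
}

## Exon length in nt for exon i (transcript orientation).
exon_length <- function(tm, i) tm$exons$end[i] - tm$exons$start[i]

## Exon category used by the length minima.
exon_category <- function(tm, i) {
  n <- n_exons(tm)
  if (n == 1L) "first" else if (i == 1L) "first" else if (i == n) "last" else "internal"
}

## Transcript genomic span (0-based half-open).
transcript_span <- function(tm) {
  c(min(tm$exons$start), max(tm$exons$end))
}

#' Load transcript annotation
#'
#' Reads exon structures from a GTF/GFF3 file (GENCODE attribute dialect) or
#' from a simplified tab-separated exon table with columns
#' `chrom, start, end, strand, transcript_id, gene_id` (1-based inclusive
#' `start`/`end`, as in GTF). Transcripts with overlapping exons or unknown
#' strand are rejected with a diagnostic message rather than aborting the
#' whole load.
#'
#' @param path GTF/GFF3 file or exon-table TSV.
#' @param canonical_only if `TRUE`, keep only transcripts carrying the
#'   GENCODE `Ensembl_canonical` tag (GTF input only).
#' @param u12_bed optional BED file (or data.frame with `chrom,start,end`)
#'   of U12-type intron intervals; introns overlapping one are classed `U12`.
#' @return named list of [transcript_model()] objects.
#' @export
load_transcript_annotation <- function(path, canonical_only = FALSE,
                                       u12_bed = NULL) {
  is_gtf <- grepl("\\.(gtf|gff3?|gff)$", path, ignore.case = TRUE)
  if (is_gtf) {
    gr <- rtracklayer::import(path)
    ex <- gr[gr$type == "exon"]
    if (canonical_only && "tag" %in% names(S4Vectors::mcols(ex))) {
      has_tag <- vapply(ex$tag, function(t) "Ensembl_canonical" %in% t, logical(1))
      ex <- ex[has_tag]
    }
    tab <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(ex)),
      start = GenomicRanges::start(ex) - 1L,  # to 0-based half-open
      end = GenomicRanges::end(ex),
      strand = as.character(GenomicRanges::strand(ex)),
      transcript_id = ex$transcript_id,
      gene_id = if ("gene_id" %in% names(S4Vectors::mcols(ex))) ex$gene_id else NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    tab <- as.data.frame(data.table::fread(path))
    need <- c("chrom", "start", "end", "strand", "transcript_id")
    if (!all(need %in% names(tab))) {
      stop("exon table must have columns: ", paste(need, collapse = ", "))
    }
    if (!"gene_id" %in% names(tab)) tab$gene_id <- NA_character_
    tab$start <- as.integer(tab$start) - 1L  # 1-based inclusive at boundary
  }
  u12 <- NULL
  if (!is.null(u12_bed)) {
    u12 <- if (is.data.frame(u12_bed)) u12_bed else {
      b <- rtracklayer::import(u12_bed, format = "bed")
      data.frame(chrom = as.character(GenomicRanges::seqnames(b)),
                 start = GenomicRanges::start(b) - 1L,
                 end = GenomicRanges::end(b))
    }
  }
  out <- list()
  for (tid in unique(tab$transcript_id)) {
    rows <- tab[tab$transcript_id == tid, , drop = FALSE]
    strand <- unique(rows$strand)
    tm <- tryCatch({
      if (length(strand) != 1L || !strand %in% c("+", "-")) {
        stop("unknown or inconsistent strand")
      }
      transcript_model(tid, rows$gene_id[1], rows$chrom[1], strand,
                       rows$start, rows$end)
    }, error = function(e) {
      message(sprintf("rejecting transcript %s: %s", tid, conditionMessage(e)))
      NULL
    })
    if (is.null(tm)) next
    if (!is.null(u12)) tm <- apply_u12_intervals(tm, u12)
    out[[tid]] <- tm
  }
  out
}

## Mark introns overlapping any U12 interval (same contig) as class U12.
apply_u12_intervals <- function(tm, u12) {
  ins <- introns(tm)
  if (nrow(ins) == 0L) return(tm)
  u <- u12[u12$chrom == tm$chrom, , drop = FALSE]
  for (i in seq_len(nrow(ins))) {
    hit <- any(u$start < ins$end[i] & u$end > ins$start[i])
    if (hit) tm$intron_classes[i] <- "U12"
  }
  tm
}
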