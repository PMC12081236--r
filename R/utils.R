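## Internal helpers shared across modules. All window math is done on plain
## upper-case character strings; Biostrings is used at I/O boundaries and for
## reverse complement.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors. `N` is preserved.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_pyrimidine <- function(b) b %in% c("C", "T")
is_purine <- function(b) b %in% c("A", "G")

## Split a string into single characters.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## Coerce any supported genome representation to a named character vector of
## contig sequences. Accepts a named character vector, a DNAStringSet, or a
## path to an (uncompressed) FASTA file.
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(toupper(out))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(toupper(genome))
  }
  stop("genome must be a named character vector, DNAStringSet or FASTA path")
}

## Extract [start0, end0) (0-based half-open, plus strand) from a genome,
## clipping at contig bounds. Returns list(seq, clipped_left, clipped_right).
genome_slice <- function(genome, chrom, start0, end0) {
  if (!chrom %in% names(genome)) {
    stop(sprintf("contig '%s' absent from genome", chrom))
  }
  len <- nchar(genome[[chrom]])
  s <- max(0L, start0)
  e <- min(len, end0)
  seq <- if (e > s) substr(genome[[chrom]], s + 1L, e) else ""
  list(seq = seq, clipped_left = s > start0, clipped_right = e < end0)
}

## Validate a single base.
check_base <- function(b, what = "base") {
  if (!is.character(b) || length(b) != 1L || !b %in% c("A", "C", "G", "T", "N")) {
    stop(sprintf("%s must be one of A/C/G/T/N, got '%s'", what,
                 paste(b, collapse = ",")))
  }
  b
}

## A tri-state logical: TRUE / FALSE / NA ("indeterminate"). Any predicate
## touching an N base yields NA and must never be coerced to pass.
tri_and <- function(...) {
  vals <- c(...)
  if (any(vals %in% FALSE)) return(FALSE)
  if (anyNA(vals)) return(NA)
  TRUE
}

verdict <- function(x) {
  if (is.na(x)) "indeterminate" else if (isTRUE(x)) "pass" else "fail"
}
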