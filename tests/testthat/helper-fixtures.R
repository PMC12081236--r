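# Deterministic handcrafted fixtures built in code. The "toy" transcript has
# fully specified splice regions so expected window contents are known by
# construction.

# Acceptor-proximal 50-mer (-50..-1): 25 nt G/C filler without adenosines,
# a TNA branchpoint with its A at -23, an 18 nt pyrimidine PPT, C at -4 and
# the canonical YAG at -3..-1.
toy_acceptor50 <- function() {
  paste0(
    strrep("GC", 12), "G",      # -50..-26 (25 nt, no A, no TNA)
    "TGA",                      # -25..-23, branchpoint A at -23
    "TCTTTCTTCTTTCTTCTT",       # -22..-5 (18 pyrimidines)
    "C",                        # -4
    "CAG"                       # -3..-1
  )
}

toy_pieces <- function() {
  list(
    lead = strrep("ACGT", 5),                              # 20 nt
    exon1 = paste0(strrep("GATTACA", 5), "AG", "CAG"),     # 40 nt, ends CAG
    intron1 = paste0("GTAAGT", strrep("CAGT", 11), toy_acceptor50()),  # 100 nt
    exon2 = paste0("G", strrep("CTGA", 9), "CAG"),         # 40 nt, G first, CAG last
    intron2 = paste0("GTAAGT", strrep("TGCA", 6), toy_acceptor50()),   # 80 nt
    exon3 = paste0("G", strrep("TTAGC", 25), "ACGT"),      # 130 nt
    tail = strrep("TGCA", 5)                               # 20 nt
  )
}

# Returns list(tm, genome, pieces, coords): a 3-exon plus-strand transcript.
toy_transcript <- function(strand = "+") {
  p <- toy_pieces()
  lens <- vapply(p, nchar, integer(1))
  stopifnot(lens[["intron1"]] == 100L, lens[["intron2"]] == 80L)
  contig <- paste(unlist(p), collapse = "")
  s1 <- lens[["lead"]]
  e1 <- s1 + lens[["exon1"]]
  s2 <- e1 + lens[["intron1"]]
  e2 <- s2 + lens[["exon2"]]
  s3 <- e2 + lens[["intron2"]]
  e3 <- s3 + lens[["exon3"]]
  tm <- transcript_model("TOY1", "GTOY", "chrT", "+", c(s1, s2, s3),
                         c(e1, e2, e3))
  genome <- stats::setNames(contig, "chrT")
  out <- list(tm = tm, genome = genome, pieces = p,
              coords = list(starts = c(s1, s2, s3), ends = c(e1, e2, e3)))
  if (strand == "-") {
    mir <- mirror_transcript(tm, genome)
    out$tm <- mir$tm
    out$genome <- mir$genome
  }
  out
}

# SNV at a site-relative label of the toy (or any) transcript.
snv_at <- function(tm, genome, intron_index, site_class, label, alt_sense) {
  pos <- heurosplice:::rel_to_genomic(tm, intron_index, site_class, label)
  ref_plus <- substr(genome[[tm$chrom]], pos, pos)
  alt_plus <- if (tm$strand == "+") alt_sense else revcomp(alt_sense)
  variant_record(tm$chrom, pos, ref_plus, alt_plus)
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
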