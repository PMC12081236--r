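## Deterministic synthetic-data generator: checklist-compliant transcripts on
## synthetic contigs, targeted variant panels (the inverse of classify_snv),
## and labeled evidence tables with known ground truth. Everything is seeded;
## the same seed yields byte-identical output.

#' Generator configuration
#'
#' Defaults state the simulated world: intron lengths of at least 100 nt
#' (comfortably above the 80 nt requirement), internal exons of 80-200 nt,
#' donor/acceptor motifs sampled from the same frequency tables as the
#' bundled scoring model (so generated sites score high by construction), a
#' planted TNA branchpoint 20-40 nt upstream of each acceptor, and a
#' polypyrimidine tract sampled at 85% pyrimidine content. `degenerate`
#' mode samples motifs uniformly to produce checklist failures for negative
#' tests.
#'
#' @param seed integer seed; same seed, same bytes.
#' @param n_exons exons per transcript.
#' @param intron_length,internal_exon,first_exon,last_exon length ranges.
#' @param ppt_py_prob pyrimidine probability in the PPT window.
#' @param bp_distance branchpoint A distance range from the 3'SS.
#' @param strand `"+"` or `"-"`.
#' @param degenerate uniform motif sampling (checklist non-compliant).
#' @param spliceogenicity_map named vector of true per-subgroup p (percent);
#'   defaults to the bundled annotations.
#' @param outcome_map named fractions for outcome marginals; defaults to the
#'   bundled global profile.
#' @param multi_outcome_rate probability that an SAV reports two outcomes.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_exons = 5L,
                             intron_length = c(100L, 300L),
                             internal_exon = c(80L, 200L),
                             first_exon = c(60L, 150L),
                             last_exon = c(150L, 300L),
                             ppt_py_prob = 0.85,
                             bp_distance = c(20L, 40L),
                             strand = "+",
                             degenerate = FALSE,
                             spliceogenicity_map = NULL,
                             outcome_map = NULL,
                             multi_outcome_rate = 0.191) {
  tab <- load_rule_table()
  if (is.null(spliceogenicity_map)) {
    spliceogenicity_map <- stats::setNames(
      tab$annotations$p, paste(tab$annotations$rule_id, tab$annotations$subgroup))
  }
  if (is.null(outcome_map)) {
    outcome_map <- unlist(tab$outcome_profiles$global)
  }
  stopifnot(all(outcome_map >= 0 & outcome_map <= 1),
            multi_outcome_rate >= 0, multi_outcome_rate <= 1)
  structure(list(seed = as.integer(seed), n_exons = n_exons,
                 intron_length = intron_length, internal_exon = internal_exon,
                 first_exon = first_exon, last_exon = last_exon,
                 ppt_py_prob = ppt_py_prob, bp_distance = bp_distance,
                 strand = strand, degenerate = degenerate,
                 spliceogenicity_map = spliceogenicity_map,
                 outcome_map = outcome_map,
                 multi_outcome_rate = multi_outcome_rate),
            class = "generator_config")
}

rand_seq <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (n <= 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

## Sample one base per position from a frequency matrix (rows = positions).
sample_motif <- function(freq, degenerate = FALSE) {
  paste(vapply(seq_len(nrow(freq)), function(i) {
    p <- if (degenerate) rep(0.25, 4) else freq[i, ]
    sample(c("A", "C", "G", "T"), 1L, prob = p)
  }, character(1)), collapse = "")
}

#' Generate a checklist-compliant transcript on a synthetic contig
#'
#' Builds one multi-exon transcript whose donor/acceptor motifs are sampled
#' from the bundled consensus frequency tables (canonical GT/AG and the
#' acceptor YAG forced outside degenerate mode), with a planted TNA
#' branchpoint, a sampled PPT and a scrubbed AG-exclusion zone, so that
#' generated internal exons pass the manual checklist with high probability.
#'
#' @param config a [generator_config()].
#' @param contig_name contig name for the emitted sequence.
#' @return list with `tm` ([transcript_model()]), `genome` (named character
#'   vector) and `truth` (per-intron planted features).
#' @export
generate_compliant_transcript <- function(config = generator_config(),
                                          contig_name = "chrSIM") {
  set.seed(config$seed)
  if (config$intron_length[1] < 62L) {
    stop("intron length range below the 62 nt theoretical minimum is infeasible")
  }
  m <- config$n_exons
  stopifnot(m >= 1L)
  donor_freq <- score_model("donor_9mer")$frequencies
  acc_freq <- score_model("acceptor_23mer")$frequencies
  rng <- function(r) if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1L)
  exon_lens <- vapply(seq_len(m), function(i) {
    r <- if (i == 1L) config$first_exon
    else if (i == m) config$last_exon else config$internal_exon
    rng(r)
  }, integer(1))
  intron_lens <- vapply(seq_len(max(0L, m - 1L)), function(i)
    rng(config$intron_length), integer(1))

  pieces <- character(0)
  truth <- list()
  lead <- rand_seq(100L)
  pieces <- c(pieces, lead)
  offset <- nchar(lead)
  exon_starts <- integer(m); exon_ends <- integer(m)
  for (i in seq_len(m)) {
    ex <- chars(rand_seq(exon_lens[i]))
    if (i > 1L && !config$degenerate) {
      ## acceptor exonic side: E+1 sampled from the acceptor table
      ex[1] <- sample(c("A", "C", "G", "T"), 1L, prob = acc_freq["E+1", ])
    }
    if (i < m) {
      don <- chars(sample_motif(donor_freq, config$degenerate))
      if (!config$degenerate) { don[4] <- "G"; don[5] <- "T" }
      ex[(exon_lens[i] - 2L):exon_lens[i]] <- don[1:3]
    }
    exon_starts[i] <- offset
    exon_ends[i] <- offset + exon_lens[i]
    pieces <- c(pieces, paste(ex, collapse = ""))
    offset <- offset + exon_lens[i]
    if (i < m) {
      iv <- chars(rand_seq(intron_lens[i]))
      M <- intron_lens[i]
      if (i <= length(truth) + 1L) truth[[i]] <- list()
      if (!config$degenerate) {
        don <- chars(sample_motif(donor_freq, FALSE))
        don[4] <- "G"; don[5] <- "T"
        iv[1:6] <- don[4:9]
        ## PPT -24..-5
        for (d in 24:5) {
          py <- stats::runif(1) < config$ppt_py_prob
          iv[M - d + 1L] <- if (py) sample(c("C", "T"), 1L) else sample(c("A", "G"), 1L)
        }
        ## branchpoint TNA, A at distance bp_d
        bp_d <- rng(config$bp_distance)
        iv[M - bp_d + 1L] <- "A"
        iv[M - bp_d] <- sample(c("A", "C", "G", "T"), 1L)   # N of T-N-A
        iv[M - bp_d - 1L] <- "T"
        ## acceptor motif Y A G at -3..-1
        iv[M - 2L] <- sample(c("C", "T"), 1L)
        iv[M - 1L] <- "A"
        iv[M] <- "G"
        ## scrub the AG-exclusion zone (A at -13..-6 followed by G)
        for (d in 13:6) {
          if (iv[M - d + 1L] == "A" && iv[M - d + 2L] == "G") {
            iv[M - d + 2L] <- "T"
          }
        }
        truth[[i]] <- list(bp_distance = bp_d, donor_9mer = paste(don, collapse = ""),
                           intron_length = M)
      } else {
        truth[[i]] <- list(intron_length = M)
      }
      pieces <- c(pieces, paste(iv, collapse = ""))
      offset <- offset + M
    }
  }
  pieces <- c(pieces, rand_seq(100L))
  contig <- paste(pieces, collapse = "")
  tm <- transcript_model("TSIM1", "GSIM1", contig_name, "+",
                         exon_starts, exon_ends)
  genome <- stats::setNames(contig, contig_name)
  if (config$strand == "-") {
    mir <- mirror_transcript(tm, genome)
    tm <- mir$tm; genome <- mir$genome
  }
  list(tm = tm, genome = genome, truth = truth)
}

#' Mirror a transcript to the opposite strand
#'
#' Reverse-complements the contig and remaps exon coordinates so that the
#' transcript's sense sequence (and thus every relative position and
#' classification) is unchanged. Used by the strand-equivalence tests.
#'
#' @param tm a [transcript_model()].
#' @param genome named character vector containing `tm$chrom`.
#' @return list with mirrored `tm` and `genome`.
#' @export
mirror_transcript <- function(tm, genome) {
  L <- nchar(genome[[tm$chrom]])
  genome[[tm$chrom]] <- revcomp(genome[[tm$chrom]])
  new_starts <- L - tm$exons$end
  new_ends <- L - tm$exons$start
  tm2 <- transcript_model(tm$transcript_id, tm$gene_id, tm$chrom,
                          if (tm$strand == "+") "-" else "+",
                          new_starts, new_ends, tm$intron_classes)
  list(tm = tm2, genome = genome)
}

## Mirror a plus-strand genomic position (1-based) for mirror_transcript.
mirror_position <- function(pos, contig_length) contig_length - pos + 1L

## Set the sense-strand base at a site-relative label (edits the genome).
set_sense_base <- function(genome, tm, intron_index, site_class, label, base) {
  pos <- rel_to_genomic(tm, intron_index, site_class, label)
  b_plus <- if (tm$strand == "+") base else revcomp(base)
  substr(genome[[tm$chrom]], pos, pos) <- b_plus
  genome
}

## Sense-strand base at a site-relative label.
get_sense_base <- function(genome, tm, intron_index, site_class, label) {
  pos <- rel_to_genomic(tm, intron_index, site_class, label)
  b <- substr(genome[[tm$chrom]], pos, pos)
  if (tm$strand == "+") b else revcomp(b)
}

## Per-subgroup construction recipes: context edits (sense bases to plant)
## and the variant to apply, both in site-relative labels.
panel_recipes <- function() {
  list(
    "DD2 standard" = list(site = "donor", edits = list(),
                          var = c("+1", "G", "A")),
    "DD1 standard" = list(site = "donor",
                          edits = list(c("+2", "C"), c("E-3", "T"), c("+6", "A")),
                          var = c("+1", "G", "A")),
    "DD1 context" = list(site = "donor", edits = list(c("+2", "C")),
                         var = c("+2", "C", "T")),
    "DD5 standard" = list(site = "donor",
                          edits = list(c("+3", "A"), c("+4", "T")),
                          var = c("+3", "A", "G")),
    "DD8 standard" = list(site = "donor",
                          edits = list(c("+3", "A"), c("+4", "A")),
                          var = c("+3", "A", "C")),
    "DD8 auxiliary" = list(site = "donor",
                           edits = list(c("+3", "C"), c("+4", "A")),
                           var = c("+3", "C", "A")),
    "DD4 standard" = list(site = "donor",
                          edits = list(c("+5", "G"), c("E-1", "C")),
                          var = c("+5", "G", "A")),
    "DD6 standard" = list(site = "donor",
                          edits = list(c("+5", "G"), c("E-1", "G")),
                          var = c("+5", "G", "A")),
    "DD6 auxiliary" = list(site = "donor", edits = list(c("+5", "A")),
                           var = c("+5", "A", "T")),
    "DD7 standard" = list(site = "donor", edits = list(c("E-1", "A")),
                          var = c("E-1", "A", "T")),
    "DD7 auxiliary" = list(site = "donor", edits = list(c("E-1", "A")),
                           var = c("E-1", "A", "G")),
    "DA2 standard" = list(site = "acceptor", edits = list(),
                          var = c("-1", "G", "C")),
    "DA3 standard" = list(site = "acceptor",
                          edits = list(c("E+1", "G"), c("-3", "A")),
                          var = c("E+1", "G", "T")),
    "DA6 standard" = list(site = "acceptor",
                          edits = list(c("E+1", "G"), c("-3", "C")),
                          var = c("E+1", "G", "T")),
    "DA6 auxiliary" = list(site = "acceptor", edits = list(c("E+1", "A")),
                           var = c("E+1", "A", "G")),
    "DA1 standard" = list(site = "acceptor",
                          edits = list(c("-11", "T"), c("-10", "C"), c("-9", "G")),
                          var = c("-10", "C", "A")),
    "DA1 context" = list(site = "acceptor",
                         edits = c(list(c("-20", "C"), c("-19", "G")),
                                   lapply(21:29, function(d) c(paste0("-", d), "T")),
                                   list(c("-30", "A"), c("-31", "T"), c("-32", "T"))),
                         var = c("-20", "C", "A")),
    "DA1 auxiliary" = list(site = "acceptor",
                           edits = c(list(c("-20", "C"), c("-19", "G")),
                                     lapply(21:50, function(d) c(paste0("-", d), "C"))),
                           var = c("-20", "C", "A")),
    "DA9 standard" = list(site = "acceptor",
                          edits = ppt_pattern_edits("TCTATCTATCTATCTATCTAT"),
                          var = c("-15", "C", "G")),
    "DA9 context" = list(site = "acceptor",
                         edits = lapply(18:5, function(d) c(paste0("-", d), "T")),
                         var = c("-15", "T", "G")),
    "DA9 auxiliary" = list(site = "acceptor",
                           edits = ppt_pattern_edits("TCTATCTATCTATCTATCTAT"),
                           var = c("-15", "C", "T"))
  )
}

## Spell out a -24..-4 PPT pattern as label edits.
ppt_pattern_edits <- function(pattern) {
  stopifnot(nchar(pattern) == 21L)
  lapply(seq_len(21L), function(i) {
    c(paste0("-", 25L - i), substr(pattern, i, i))
  })
}

#' Generate a targeted variant panel
#'
#' The inverse of [classify_snv()]: for each requested heuristic subgroup,
#' plants the required sequence context on one intron of the transcript
#' (editing the synthetic genome) and emits an SNV guaranteed to classify
#' into that subgroup. Each emitted variant is verified internally by
#' running the classifier; unreachable requests are skipped with a
#' diagnostic.
#'
#' @param tm a [transcript_model()] with at least as many introns as
#'   requested subgroups (one intron is consumed per request).
#' @param genome named character vector (will be edited).
#' @param targets character vector of subgroup keys, e.g. `"DD2 standard"`.
#' @param rule_table a [load_rule_table()] result.
#' @return list with `variants` (list of [variant_record()]), `subgroups`
#'   (character, parallel), `genome` (edited), `skipped`.
#' @export
generate_variant_panel <- function(tm, genome, targets = NULL,
                                   rule_table = load_rule_table()) {
  recipes <- panel_recipes()
  if (is.null(targets)) targets <- names(recipes)
  n_int <- n_exons(tm) - 1L
  if (length(targets) > n_int) {
    stop(sprintf("need %d introns for %d targets, transcript has %d",
                 length(targets), length(targets), n_int))
  }
  targets <- unname(targets)
  variants <- list(); keys <- character(); skipped <- character()
  for (i in seq_along(targets)) {
    key <- targets[i]
    rec <- recipes[[key]]
    if (is.null(rec)) {
      message("no construction recipe for subgroup: ", key)
      skipped <- c(skipped, key)
      next
    }
    j <- i  # one intron per target
    for (e in rec$edits) {
      genome <- set_sense_base(genome, tm, j, rec$site, e[1], e[2])
    }
    pos <- rel_to_genomic(tm, j, rec$site, rec$var[1])
    ref_sense <- rec$var[2]; alt_sense <- rec$var[3]
    ## recipes assert the planted ref; guard against edit collisions
    have <- get_sense_base(genome, tm, j, rec$site, rec$var[1])
    if (have != ref_sense) {
      genome <- set_sense_base(genome, tm, j, rec$site, rec$var[1], ref_sense)
    }
    ref_plus <- if (tm$strand == "+") ref_sense else revcomp(ref_sense)
    alt_plus <- if (tm$strand == "+") alt_sense else revcomp(alt_sense)
    v <- variant_record(tm$chrom, pos, ref_plus, alt_plus)
    a <- classify_snv(v, tm, genome, rule_table, site_class = rec$site)
    got <- paste(a$rule_id, a$subgroup)
    if (!identical(got, key)) {
      message(sprintf("recipe for %s produced %s on intron %d; skipping",
                      key, got, j))
      skipped <- c(skipped, key)
      next
    }
    variants[[length(variants) + 1L]] <- v
    keys <- c(keys, key)
  }
  list(variants = variants, subgroups = keys, genome = genome,
       skipped = skipped)
}

## Calibrate primary-outcome weights so that the realized outcome marginals
## match the configured map under the primary + optional-extra sampling
## scheme (fixed-point iteration; deterministic).
calibrate_outcome_weights <- function(outcome_map, multi_rate, iters = 200L) {
  m <- outcome_map / sum(outcome_map) * (1 + multi_rate)  # scaled marginals
  a <- outcome_map / sum(outcome_map)
  marg <- function(a) {
    sapply(seq_along(a), function(o) {
      extra <- sum(vapply(seq_along(a), function(q) {
        if (q == o) return(0)
        a[q] * a[o] / (1 - a[q])
      }, numeric(1)))
      a[o] + multi_rate * extra
    })
  }
  for (it in seq_len(iters)) {
    p <- marg(a)
    a <- a * m / p
    a <- pmin(pmax(a, 1e-6), 1 - 1e-6)
    a <- a / sum(a)
  }
  a
}

#' Simulate labels and outcomes for a classified panel
#'
#' Labels are Bernoulli draws with the per-subgroup true spliceogenicity;
#' each splice-altering row samples one primary outcome (weights calibrated
#' so realized marginals match `config$outcome_map`) plus, with probability
#' `config$multi_outcome_rate`, a second distinct outcome.
#'
#' @param panel a [generate_variant_panel()] result, or any list with
#'   `variants` and `subgroups`.
#' @param config a [generator_config()] (its `seed` drives the draws).
#' @param n_replicates rows to draw per panel variant; either a scalar or a
#'   vector parallel to `panel$variants` (e.g. the bundled per-subgroup n).
#' @return data.frame in the evidence-table dialect (plus `subgroup`), with
#'   `outcomes` as comma-separated strings.
#' @export
generate_labeled_table <- function(panel, config = generator_config(),
                                   n_replicates = 1L) {
  set.seed(config$seed + 1L)
  if (length(n_replicates) == 1L) {
    n_replicates <- rep(n_replicates, length(panel$variants))
  }
  stopifnot(length(n_replicates) == length(panel$variants))
  keys <- rep(panel$subgroups, times = n_replicates)
  vars <- rep(panel$variants, times = n_replicates)
  p_map <- config$spliceogenicity_map
  missing_p <- setdiff(unique(keys), names(p_map))
  if (length(missing_p)) {
    stop("no true spliceogenicity for subgroup(s): ",
         paste(missing_p, collapse = ", "))
  }
  a <- calibrate_outcome_weights(config$outcome_map, config$multi_outcome_rate)
  outs <- names(config$outcome_map)
  n <- length(keys)
  label <- stats::rbinom(n, 1L, p_map[keys] / 100) == 1L
  outcomes <- character(n)
  for (i in seq_len(n)) {
    if (!label[i]) { outcomes[i] <- ""; next }
    o <- sample(outs, 1L, prob = a)
    if (stats::runif(1) < config$multi_outcome_rate && length(outs) > 1L) {
      rest <- setdiff(outs, o)
      o <- c(o, sample(rest, 1L, prob = a[match(rest, outs)]))
    }
    outcomes[i] <- paste(sort(o), collapse = ",")
  }
  data.frame(
    chrom = vapply(vars, `[[`, character(1), "chrom"),
    pos = vapply(vars, `[[`, integer(1), "pos"),
    ref = vapply(vars, `[[`, character(1), "ref"),
    alt = vapply(vars, `[[`, character(1), "alt"),
    genome_build = "synthetic",
    classification = ifelse(label, "splice-altering", "normal"),
    outcomes = ifelse(label, ifelse(outcomes == "", "none", outcomes), ""),
    method = "simulation",
    subgroup = keys
  )
}

#' Write a simulated dataset to standard formats
#'
#' Emits FASTA (contig), GTF (exons), VCF (panel variants) and the evidence
#' TSV for one simulated transcript + panel.
#'
#' @param dir output directory (created).
#' @param sim a [generate_compliant_transcript()] result.
#' @param panel a [generate_variant_panel()] result (optional).
#' @param table a [generate_labeled_table()] result (optional).
#' @return invisibly, the paths written.
#' @export
write_simulated_dataset <- function(dir, sim, panel = NULL, table = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  genome <- if (!is.null(panel)) panel$genome else sim$genome
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fa)
  paths <- c(paths, fa)
  tm <- sim$tm
  gr <- GenomicRanges::GRanges(
    seqnames = tm$chrom,
    ranges = IRanges::IRanges(start = tm$exons$start + 1L, end = tm$exons$end),
    strand = tm$strand, type = "exon",
    source = "heurosplice_sim",
    transcript_id = tm$transcript_id, gene_id = tm$gene_id)
  gtf <- file.path(dir, "transcripts.gtf")
  rtracklayer::export(gr, gtf, format = "gtf")
  paths <- c(paths, gtf)
  if (!is.null(panel) && length(panel$variants)) {
    vcf <- file.path(dir, "variants.vcf")
    lines <- c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", tm$chrom,
                       nchar(genome[[tm$chrom]])),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    for (i in seq_along(panel$variants)) {
      v <- panel$variants[[i]]
      lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", v$chrom, v$pos,
                                paste0("sim", i), v$ref, v$alt))
    }
    writeLines(lines, vcf)
    paths <- c(paths, vcf)
  }
  if (!is.null(table)) {
    tsv <- file.path(dir, "evidence.tsv")
    data.table::fwrite(table, tsv, sep = "\t")
    paths <- c(paths, tsv)
  }
  invisible(paths)
}
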