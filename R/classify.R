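## The donor-disruption (DD) / acceptor-disruption (DA) classification engine.
## Rules are data (see rules.R); this file implements the predicate vocabulary
## and the per-site evaluation walk.

DONOR_LABELS <- c("E-3", "E-2", "E-1", paste0("+", 1:6))
ACCEPTOR_LABELS <- c(paste0("-", 50:1), "E+1")

#' Compare reference and alternative bases under a base cascade
#'
#' Base cascades are per-position nucleotide preference orderings (for
#' example `G>A>C>T` at the last exonic base). The comparison reports the
#' status of the alternative base relative to the reference: an `A>T` change
#' under `G>A>C>T` yields `"less_preferred"`.
#'
#' @param ref_base,alt_base single bases.
#' @param cascade named numeric rank vector over `A,C,G,T` (rank 1 = most
#'   preferred; equal ranks encode ties), or a cascade name when
#'   `rule_table` is supplied.
#' @param rule_table optional [load_rule_table()] result for name lookup.
#' @return `"more_preferred"`, `"less_preferred"` or `"equal"`; `NA` for N.
#' @export
cascade_compare <- function(ref_base, alt_base, cascade,
                            rule_table = NULL) {
  if (is.character(cascade) && length(cascade) == 1L) {
    rule_table <- rule_table %||% load_rule_table()
    cascade <- rule_table$cascades[[cascade]]
    if (is.null(cascade)) stop("unknown cascade")
  }
  if (ref_base == "N" || alt_base == "N") return(NA_character_)
  r <- cascade[[ref_base]]; a <- cascade[[alt_base]]
  if (a < r) "more_preferred" else if (a > r) "less_preferred" else "equal"
}

#' Dinucleotide motifs created by a variant
#'
#' Given aligned reference and alternative context strings, reports every
#' position (1-based index of the first base, or its label when `labels` is
#' given) where the motif exists in the alternative but not the reference.
#'
#' @param ref_context,alt_context equal-length sense-strand strings.
#' @param motif 2 nt motif, e.g. `"AG"`.
#' @param labels optional character vector of per-position labels.
#' @return integer positions or labels (possibly empty).
#' @export
creates_dinucleotide <- function(ref_context, alt_context, motif,
                                 labels = NULL) {
  stopifnot(nchar(ref_context) == nchar(alt_context), nchar(motif) == 2L)
  n <- nchar(ref_context)
  hits <- integer()
  for (i in seq_len(max(0L, n - 1L))) {
    a <- substr(alt_context, i, i + 1L)
    r <- substr(ref_context, i, i + 1L)
    if (a == motif && r != motif) hits <- c(hits, i)
  }
  if (is.null(labels)) hits else labels[hits]
}

destroys_dinucleotide_at <- function(ref_context, alt_context, motif) {
  creates_dinucleotide(alt_context, ref_context, motif)
}

## ---- evaluation context ---------------------------------------------------

## Sense-strand window string over a fixed label range around one splice
## site. Contiguous in the genome; contig overruns padded with N.
site_window_seq <- function(tm, genome, intron_index, site_class) {
  labels <- if (site_class == "donor") DONOR_LABELS else ACCEPTOR_LABELS
  p1 <- rel_to_genomic(tm, intron_index, site_class, labels[1])
  p2 <- rel_to_genomic(tm, intron_index, site_class, labels[length(labels)])
  w <- sense_window(genome, tm, min(p1, p2) - 1L, max(p1, p2))
  list(labels = labels, seq = w$sense)
}

## Build the evaluation context for one (variant position, site) pair.
## ref_base/alt_base are in transcript sense orientation. `tm_alt`/`genome_alt`
## let indels re-extract the alternative window around the preserved boundary.
build_eval_ctx <- function(tm, genome, intron_index, site_class, label,
                           ref_base, alt_base, rule_table,
                           alt_window = NULL) {
  labels <- if (site_class == "donor") DONOR_LABELS else ACCEPTOR_LABELS
  win <- site_window_seq(tm, genome, intron_index, site_class)
  ref <- win$seq
  idx <- match(label, labels)
  if (is.na(idx)) stop("label ", label, " outside ", site_class, " window")
  have <- substr(ref, idx, idx)
  if (!is.na(ref_base) && have != "N" && have != ref_base) {
    stop(sprintf("REF mismatch at %s (%s site of intron %d): expected '%s', genome has '%s'",
                 label, site_class, intron_index, ref_base, have))
  }
  if (is.null(alt_window)) {
    alt <- ref
    substr(alt, idx, idx) <- alt_base
  } else {
    alt <- alt_window
  }
  env <- new.env(parent = emptyenv())
  env$tm <- tm; env$genome <- genome; env$intron_index <- intron_index
  env$site_class <- site_class; env$label <- label; env$labels <- labels
  env$ref <- ref; env$alt <- alt
  env$ref_base <- if (is.na(ref_base)) have else ref_base
  env$alt_base <- alt_base
  env$rule_table <- rule_table
  env$created <- character(0)
  env
}

## Label helpers for window-range checks.
label_in_range <- function(label, from, to) {
  if (label_kind(label) != label_kind(from)) return(FALSE)
  k <- label_offset(label)
  k >= min(label_offset(from), label_offset(to)) &&
    k <= max(label_offset(from), label_offset(to))
}

## Acceptor-side intronic string (-50..-1) = first 50 chars of the window.
acceptor_intron_part <- function(seqs) substr(seqs, 1L, 50L)

## ---- predicate evaluation -------------------------------------------------

eval_predicate <- function(pr, ctx) {
  tab <- ctx$rule_table
  switch(pr$pred,
    ref_base_is = {
      if (ctx$ref_base == "N") NA else ctx$ref_base %in% unlist(pr$bases)
    },
    alt_base_is = {
      if (ctx$alt_base == "N") NA else ctx$alt_base %in% unlist(pr$bases)
    },
    gc_donor = ,
    gt_donor = {
      i1 <- match("+1", ctx$labels)
      dn <- substr(ctx$ref, i1, i1 + 1L)
      if (grepl("N", dn)) NA else dn == (if (pr$pred == "gc_donor") "GC" else "GT")
    },
    context_base = {
      i <- match(pr$at, ctx$labels)
      if (is.na(i)) stop("context position ", pr$at, " outside window")
      b <- substr(ctx$ref, i, i)
      if (b == "N") NA else b %in% unlist(pr$bases)
    },
    cascade_compare = {
      comp <- cascade_compare(ctx$ref_base, ctx$alt_base,
                              tab$cascades[[pr$cascade]])
      if (is.na(comp)) NA else comp %in% unlist(pr$result)
    },
    creates_dinucleotide = {
      hits <- creates_dinucleotide(ctx$ref, ctx$alt, pr$motif, ctx$labels)
      win <- unlist(pr$window)
      hits <- hits[vapply(hits, label_in_range, logical(1), win[1], win[2])]
      if (length(hits)) { ctx$created <- hits; TRUE } else FALSE
    },
    destroys_dinucleotide = {
      hits <- destroys_dinucleotide_at(ctx$ref, ctx$alt, pr$motif)
      hits <- ctx$labels[hits]
      win <- unlist(pr$window)
      any(vapply(hits, label_in_range, logical(1), win[1], win[2]))
    },
    ppt_is_strong = {
      count_ppt(acceptor_intron_part(ctx$ref))$is_strong
    },
    bp_proximity = {
      ## created AG at least `min_downstream` nt downstream of the closest
      ## upstream branchpoint A (permissive YNA motif for this predicate)
      if (length(ctx$created) == 0L) return(FALSE)
      bps <- find_branchpoints(acceptor_intron_part(ctx$ref), motif = "YNA")
      if (nrow(bps) == 0L) return(FALSE)
      any(vapply(ctx$created, function(lb) {
        d_c <- label_offset(lb)
        ups <- bps$distance[bps$distance > d_c]
        length(ups) > 0L && (min(ups) - d_c) >= pr$min_downstream
      }, logical(1)))
    },
    bp_destroyed = {
      before <- nrow(find_branchpoints(acceptor_intron_part(ctx$ref)))
      after <- nrow(find_branchpoints(acceptor_intron_part(ctx$alt)))
      before >= 1L && after == 0L
    },
    motif_match_count = {
      i1 <- match(if (ctx$site_class == "donor") "E-3" else stop("donor only"),
                  ctx$labels)
      alt9 <- substr(ctx$alt, i1, i1 + 8L)
      cfg <- checklist_config()
      n1 <- sum(chars(alt9) == chars(cfg$donor_consensus))
      n2 <- sum(chars(alt9) == chars(cfg$gc_donor_consensus))
      max(n1, n2) >= pr$min
    },
    stop("unknown predicate: ", pr$pred)
  )
}

describe_predicate <- function(pr, outcome) {
  what <- switch(pr$pred,
    ref_base_is = paste0("ref in {", paste(unlist(pr$bases), collapse = ","), "}"),
    alt_base_is = paste0("alt in {", paste(unlist(pr$bases), collapse = ","), "}"),
    gc_donor = "GC donor",
    gt_donor = "GT donor",
    context_base = paste0(pr$at, " in {", paste(unlist(pr$bases), collapse = ","), "}"),
    cascade_compare = paste0("alt ", paste(unlist(pr$result), collapse = "/"),
                             " under ", pr$cascade, " cascade"),
    creates_dinucleotide = paste0("creates ", pr$motif, " in ",
                                  paste(unlist(pr$window), collapse = "..")),
    destroys_dinucleotide = paste0("destroys ", pr$motif, " in ",
                                   paste(unlist(pr$window), collapse = "..")),
    ppt_is_strong = "PPT is strong",
    bp_proximity = paste0("created AG >= ", pr$min_downstream,
                          " nt downstream of closest branchpoint A"),
    bp_destroyed = "sole branchpoint motif destroyed",
    motif_match_count = paste0("alt motif matches >= ", pr$min, "/9 consensus"),
    pr$pred)
  paste0(what, " -> ", if (is.na(outcome)) "indeterminate" else if (outcome) "yes" else "no")
}

## ---- assignments ----------------------------------------------------------

subgroup_assignment <- function(rule_id = NA_character_,
                                subgroup = NA_character_, annotation = NULL,
                                trace = character(), flags = character(),
                                site_class = NA_character_,
                                intron_index = NA_integer_,
                                label = NA_character_, variant = NULL) {
  structure(list(rule_id = rule_id, subgroup = subgroup,
                 annotation = annotation, trace = trace, flags = flags,
                 site_class = site_class, intron_index = intron_index,
                 label = label, variant = variant),
            class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  if (is.na(x$rule_id)) {
    cat(sprintf("<subgroup_assignment> no rule (%s)\n",
                paste(x$flags, collapse = ",")))
  } else {
    a <- x$annotation
    cat(sprintf("<subgroup_assignment> %s %s at %s (%s site)", x$rule_id,
                x$subgroup, x$label, x$site_class))
    if (!is.null(a)) {
      cat(sprintf(": spliceogenicity %.1f%% [%.1f-%.1f] n=%d", a$p, a$ci[1],
                  a$ci[2], a$n))
    }
    cat("\n")
    if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  }
  invisible(x)
}

## Walk the decision path for one label. Returns a subgroup_assignment.
evaluate_path <- function(ctx, rule_table) {
  path <- NULL
  for (p in rule_table$paths[[ctx$site_class]]) {
    if (ctx$label %in% p$labels) { path <- p; break }
  }
  if (is.null(path)) {
    return(subgroup_assignment(flags = "not_covered",
                               site_class = ctx$site_class,
                               intron_index = ctx$intron_index,
                               label = ctx$label))
  }
  trace <- sprintf("variant at %s (%s site)", ctx$label, ctx$site_class)
  for (br in path$branches) {
    ok <- TRUE
    ctx$created <- character(0)
    for (pr in br$when) {
      res <- eval_predicate(pr, ctx)
      trace <- c(trace, describe_predicate(pr, res))
      if (is.na(res)) {
        return(subgroup_assignment(br$assign[[1]], br$assign[[2]],
                                   trace = trace, flags = "indeterminate",
                                   site_class = ctx$site_class,
                                   intron_index = ctx$intron_index,
                                   label = ctx$label))
      }
      if (!res) { ok <- FALSE; break }
    }
    if (ok) {
      ann <- rule_annotation(rule_table, br$assign[[1]], br$assign[[2]])
      trace <- c(trace, sprintf("%s %s", br$assign[[1]], br$assign[[2]]))
      return(subgroup_assignment(br$assign[[1]], br$assign[[2]], ann,
                                 trace = trace,
                                 site_class = ctx$site_class,
                                 intron_index = ctx$intron_index,
                                 label = ctx$label))
    }
  }
  subgroup_assignment(flags = "not_covered", trace = trace,
                      site_class = ctx$site_class,
                      intron_index = ctx$intron_index, label = ctx$label)
}

## Offset distance of a label to its splice-site boundary (for picking the
## primary site when a variant sits in two windows).
label_distance <- function(label) label_offset(label)

#' Classify a single-nucleotide variant
#'
#' Maps the variant to its splice-site-relative position, routes it through
#' the donor- or acceptor-disruption decision tree and returns the assigned
#' heuristic subgroup with its bundled spliceogenicity annotation and the
#' full predicate trace. Variants outside every heuristic window come back
#' unassigned with an explanatory flag (`deep_intronic` - candidate for the
#' pseudoexon pathway - or `SRE_not_covered` for exonic positions away from
#' the splice sites). Variants in U12-class introns are flagged
#' `U12_unsupported` and not assigned.
#'
#' @param variant a [variant_record()] (SNV).
#' @param tm a [transcript_model()].
#' @param genome genome (named character vector, `DNAStringSet`, FASTA path).
#' @param rule_table a [load_rule_table()] result.
#' @param site_class optional `"donor"`/`"acceptor"` to force one side when a
#'   variant sits in both windows; default picks the nearer site (donor on a
#'   tie) and stores the other assignment in `$secondary`.
#' @return a `subgroup_assignment`.
#' @export
classify_snv <- function(variant, tm, genome, rule_table = load_rule_table(),
                         site_class = NULL) {
  stopifnot(inherits(variant, "variant_record"))
  if (variant$variant_class != "SNV") stop("classify_snv requires an SNV")
  genome <- as_genome(genome)
  if (variant$chrom != tm$chrom) {
    return(subgroup_assignment(flags = "intergenic", variant = variant))
  }
  maps <- site_windows(tm, variant$pos)
  if (!is.null(site_class)) maps <- maps[maps$site_class == site_class, , drop = FALSE]
  if (nrow(maps) == 0L) {
    loc <- locate_position(variant$pos, tm)
    flag <- if (is.null(loc)) "intergenic"
    else if (loc$where == "intron") "deep_intronic"
    else "SRE_not_covered"
    return(subgroup_assignment(flags = flag, variant = variant))
  }
  ## nearer site first; donor wins ties
  ord <- order(vapply(maps$label, label_distance, numeric(1)),
               match(maps$site_class, c("donor", "acceptor")))
  maps <- maps[ord, , drop = FALSE]
  sense_ref <- if (tm$strand == "+") variant$ref else revcomp(variant$ref)
  sense_alt <- if (tm$strand == "+") variant$alt else revcomp(variant$alt)
  res <- lapply(seq_len(nrow(maps)), function(i) {
    j <- maps$intron_index[i]
    if (tm$intron_classes[j] == "U12") {
      return(subgroup_assignment(flags = "U12_unsupported",
                                 site_class = maps$site_class[i],
                                 intron_index = j, label = maps$label[i],
                                 variant = variant))
    }
    ctx <- build_eval_ctx(tm, genome, j, maps$site_class[i], maps$label[i],
                          sense_ref, sense_alt, rule_table)
    a <- evaluate_path(ctx, rule_table)
    a$variant <- variant
    a
  })
  primary <- res[[1]]
  if (length(res) > 1L) attr(primary, "secondary") <- res[-1L]
  primary
}

#' Classify an insertion, deletion or delins
#'
#' Indels can touch several heuristic positions at once. The alternative
#' sequence is rebuilt around each preserved splice-site boundary, every
#' window position whose base changes is evaluated through its decision
#' path, and the summary is the match with the highest spliceogenicity (all
#' matches are retained).
#'
#' @inheritParams classify_snv
#' @return list with `assignments` (all matches) and `summary` (maximum-
#'   spliceogenicity assignment, or an unassigned record with a flag).
#' @export
classify_indel <- function(variant, tm, genome, rule_table = load_rule_table()) {
  stopifnot(inherits(variant, "variant_record"))
  if (variant$variant_class == "SNV") stop("use classify_snv for SNVs")
  genome <- as_genome(genome)
  vs0 <- variant$pos - 1L
  ve0 <- vs0 + nchar(variant$ref)
  shift <- nchar(variant$alt) - nchar(variant$ref)
  ## reject indels swallowing a whole exon
  for (i in seq_len(n_exons(tm))) {
    if (vs0 <= tm$exons$start[i] && ve0 >= tm$exons$end[i]) {
      return(list(assignments = list(),
                  summary = subgroup_assignment(flags = "not_covered",
                                                variant = variant)))
    }
  }
  ## edited contig + coordinate-shifted transcript
  contig <- genome[[tm$chrom]]
  have <- substr(contig, vs0 + 1L, ve0)
  if (!identical(have, variant$ref)) {
    stop(sprintf("REF mismatch at %s:%d: expected '%s', genome has '%s'",
                 variant$chrom, variant$pos, variant$ref, have))
  }
  alt_contig <- paste0(substr(contig, 1L, vs0), variant$alt,
                       substr(contig, ve0 + 1L, nchar(contig)))
  genome_alt <- genome
  genome_alt[[tm$chrom]] <- alt_contig
  shift_coord <- function(cc) {
    ifelse(cc <= vs0, cc,
           ifelse(cc >= ve0, cc + shift,
                  vs0 + pmin(cc - vs0, nchar(variant$alt))))
  }
  tm_alt <- tm
  tm_alt$exons$start <- as.integer(shift_coord(tm$exons$start))
  tm_alt$exons$end <- as.integer(shift_coord(tm$exons$end))

  out <- list()
  ins <- introns(tm)
  for (j in seq_len(nrow(ins))) {
    if (tm$intron_classes[j] == "U12") next
    for (sc in c("donor", "acceptor")) {
      refw <- site_window_seq(tm, genome, j, sc)$seq
      altw <- site_window_seq(tm_alt, genome_alt, j, sc)$seq
      if (identical(refw, altw)) next
      labels <- if (sc == "donor") DONOR_LABELS else ACCEPTOR_LABELS
      for (i in seq_along(labels)) {
        rb <- substr(refw, i, i); ab <- substr(altw, i, i)
        if (rb == ab) next
        ctx <- build_eval_ctx(tm, genome, j, sc, labels[i], rb, ab,
                              rule_table, alt_window = altw)
        a <- evaluate_path(ctx, rule_table)
        a$variant <- variant
        if (!is.na(a$rule_id) || length(a$flags)) out[[length(out) + 1L]] <- a
      }
    }
  }
  assigned <- Filter(function(a) !is.na(a$rule_id) && !is.null(a$annotation), out)
  summary <- if (length(assigned)) {
    ps <- vapply(assigned, function(a) a$annotation$p, numeric(1))
    assigned[[which.max(ps)]]
  } else if (length(out)) {
    out[[1]]
  } else {
    loc <- locate_position(variant$pos, tm)
    flag <- if (is.null(loc)) "intergenic"
    else if (loc$where == "intron") "deep_intronic" else "SRE_not_covered"
    subgroup_assignment(flags = flag, variant = variant)
  }
  list(assignments = out, summary = summary)
}
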