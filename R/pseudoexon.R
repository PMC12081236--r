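## Deep-intronic variant assessment: mechanism attribution and partner
## splice-site search for pseudoexon prediction.
##
## A pseudoexon is an intronic segment recognized as an exon after a deep
## intronic variant creates or strengthens splice signals. Candidate partner
## sites pair a 3'SS (AG) with a downstream 5'SS (GT) so that the implied
## exon is 31-750 nt long; partners are kept when they reach 75% of the
## model's maximum score, or >= 3 bits when within 200 nt of the new site.

#' Pseudoexon search configuration
#'
#' @param min_exon_nt,max_exon_nt implied exon length window (31-750 nt).
#' @param strength_fraction fraction of [model_max_score()] a partner must
#'   reach (0.75).
#' @param relax_distance_nt,relax_min_score proximity relaxation: partners
#'   within this distance of the new site only need this absolute score.
#' @param strengthen_min_delta minimum score gain (bits) to call a
#'   pre-existing site "strengthened" (guards against float noise).
#' @param scan_radius_nt how far around the variant to look for candidate
#'   sites and partners.
#' @return list of class `pseudoexon_config`.
#' @export
pseudoexon_config <- function(min_exon_nt = 31L, max_exon_nt = 750L,
                              strength_fraction = 0.75,
                              relax_distance_nt = 200L, relax_min_score = 3,
                              strengthen_min_delta = 0.1,
                              scan_radius_nt = 760L) {
  structure(list(min_exon_nt = min_exon_nt, max_exon_nt = max_exon_nt,
                 strength_fraction = strength_fraction,
                 relax_distance_nt = relax_distance_nt,
                 relax_min_score = relax_min_score,
                 strengthen_min_delta = strengthen_min_delta,
                 scan_radius_nt = scan_radius_nt),
            class = "pseudoexon_config")
}

## Does a site score satisfy the pseudoexon strength filter?
passes_strength <- function(score, max_score, distance = NA,
                            config = pseudoexon_config()) {
  if (is.na(score)) return(FALSE)
  if (score >= config$strength_fraction * max_score) return(TRUE)
  !is.na(distance) && distance <= config$relax_distance_nt &&
    score >= config$relax_min_score
}

## Sense-strand intronic region around a deep intronic variant.
## Returns list(seq, gstart0, gend0, var_index) with var_index the 1-based
## index of the variant's first REF base within the sense sequence.
variant_region <- function(variant, tm, genome, radius) {
  loc <- locate_position(variant$pos, tm)
  if (is.null(loc) || loc$where != "intron") {
    stop("variant is not intronic for this transcript")
  }
  g0 <- variant$pos - 1L - radius
  g1 <- variant$pos - 1L + nchar(variant$ref) + radius
  w <- sense_window(genome, tm, g0, g1)
  idx <- if (tm$strand == "+") variant$pos - g0
  else g1 - (variant$pos - 1L + nchar(variant$ref)) + 1L
  list(seq = w$sense, gstart0 = g0, gend0 = g1, var_index = idx,
       intron_index = loc$index)
}

## Apply a variant to a sense-strand region string (region from
## variant_region; index bookkeeping assumes the REF span is inside).
region_alt_seq <- function(region, variant, strand) {
  ref_s <- if (strand == "+") variant$ref else revcomp(variant$ref)
  alt_s <- if (strand == "+") variant$alt else revcomp(variant$alt)
  i <- region$var_index
  have <- substr(region$seq, i, i + nchar(ref_s) - 1L)
  if (!identical(have, ref_s)) {
    stop(sprintf("REF mismatch at %s:%d in pseudoexon region", variant$chrom,
                 variant$pos))
  }
  paste0(substr(region$seq, 1L, i - 1L), alt_s,
         substr(region$seq, i + nchar(ref_s), nchar(region$seq)))
}

## Map a 1-based index in a sense-strand region back to a genomic position.
region_index_to_genomic <- function(region, idx, strand) {
  if (strand == "+") region$gstart0 + idx else region$gend0 - idx + 1L
}

#' Attribute the mechanism of a deep intronic variant
#'
#' Categories, in precedence order: creation of a canonical donor GT or
#' acceptor AG dinucleotide; strengthening of a pre-existing cryptic site
#' (candidate in both Ref and Alt, score gain above the configured delta);
#' a new candidate appearing only in Alt through another route (PPT
#' strengthening, AG-exclusion-zone removal, non-canonical base change); or
#' unresolved. Splicing-regulatory-element effects are not modeled and show
#' up as `unresolved`.
#'
#' @param variant a deep intronic [variant_record()].
#' @param tm a [transcript_model()].
#' @param genome genome.
#' @param models list with `donor`/`acceptor` [score_model()]s (defaults:
#'   bundled PWM models).
#' @param config a [pseudoexon_config()].
#' @return object of class `mechanism_call` with `category`, `site_index`
#'   (position in the scanned region), `site_pos` (genomic), `site_type`,
#'   `ref_score`, `alt_score`, `notes`.
#' @export
attribute_mechanism <- function(variant, tm, genome, models = NULL,
                                config = pseudoexon_config()) {
  genome <- as_genome(genome)
  if (nrow(site_windows(tm, variant$pos)) > 0L) {
    stop("variant lies in a heuristic window; use the DD/DA pathway")
  }
  if (is.null(models)) {
    models <- list(donor = score_model("donor_9mer"),
                   acceptor = score_model("acceptor_23mer"))
  }
  region <- variant_region(variant, tm, genome, config$scan_radius_nt)
  ref <- region$seq
  alt <- region_alt_seq(region, variant, tm$strand)
  same_len <- nchar(ref) == nchar(alt)
  notes <- character()
  mk <- function(category, site_index = NA, site_type = NA, ref_score = NA,
                 alt_score = NA) {
    structure(list(category = category, site_index = site_index,
                   site_pos = if (is.na(site_index)) NA_integer_ else
                     region_index_to_genomic(region, site_index, tm$strand),
                   site_type = site_type, ref_score = ref_score,
                   alt_score = alt_score, notes = notes, region = region,
                   alt_seq = alt),
              class = "mechanism_call")
  }

  ## 1. canonical dinucleotide creation (near the variant)
  if (same_len) {
    lo <- max(1L, region$var_index - 1L)
    hi <- min(nchar(ref) - 1L, region$var_index + nchar(variant$ref))
    sub_r <- substr(ref, lo, hi + 1L); sub_a <- substr(alt, lo, hi + 1L)
    gt <- creates_dinucleotide(sub_r, sub_a, "GT") + lo - 1L
    ag <- creates_dinucleotide(sub_r, sub_a, "AG") + lo - 1L
    if (length(gt) && length(ag)) {
      notes <- c(notes, sprintf("also creates AG at region index %d", ag[1]))
    }
    if (length(gt)) {
      win <- substr(alt, gt[1] - 3L, gt[1] + 5L)
      sc <- if (nchar(win) == 9L) score_donor(win, models$donor)$value else NA
      return(mk("created_donor_GT", gt[1], "donor", alt_score = sc))
    }
    if (length(ag)) {
      win <- substr(alt, ag[1] - 18L, ag[1] + 4L)
      sc <- if (nchar(win) == 23L) score_acceptor(win, models$acceptor)$value else NA
      return(mk("created_acceptor_AG", ag[1], "acceptor", alt_score = sc))
    }
  } else {
    ## indels: compare dinucleotide content around the edit
    win_r <- substr(ref, max(1L, region$var_index - 1L),
                    min(nchar(ref), region$var_index + nchar(variant$ref) + 1L))
    win_a <- substr(alt, max(1L, region$var_index - 1L),
                    min(nchar(alt), region$var_index + nchar(variant$alt) + 1L))
    for (m in c("GT", "AG")) {
      if (grepl(m, win_a, fixed = TRUE) && !grepl(m, win_r, fixed = TRUE)) {
        idx <- region$var_index - 1L + as.integer(regexpr(m, win_a, fixed = TRUE))
        type <- if (m == "GT") "donor" else "acceptor"
        return(mk(paste0("created_", type, "_", m), idx, type))
      }
    }
    notes <- c(notes, "length-changing variant: site-strength comparison skipped")
    return(mk("unresolved"))
  }

  ## 2/3. site-strength comparison between Ref and Alt scans
  max_d <- model_max_score(models$donor)
  max_a <- model_max_score(models$acceptor)
  best <- NULL
  for (st in c("donor", "acceptor")) {
    model <- models[[st]]
    mx <- if (st == "donor") max_d else max_a
    sr <- scan_sites(ref, st, model)
    sa <- scan_sites(alt, st, model)
    merged <- merge(sr, sa, by = "dinuc_start", suffixes = c("_ref", "_alt"))
    for (k in seq_len(nrow(merged))) {
      r <- merged[k, ]
      dist <- abs(r$dinuc_start - region$var_index)
      if (passes_strength(r$score_alt, mx, dist, config) &&
          r$score_alt > r$score_ref + config$strengthen_min_delta) {
        cand <- list(category = "strengthened_existing_site", idx = r$dinuc_start,
                     type = st, ref_score = r$score_ref, alt_score = r$score_alt,
                     in_ref = passes_strength(r$score_ref, mx, dist, config))
        if (is.null(best) || cand$alt_score > best$alt_score) best <- cand
      }
    }
  }
  if (!is.null(best)) {
    category <- if (best$in_ref) "strengthened_existing_site" else "new_candidate_other"
    ## sub-mechanism annotation for acceptors: PPT / AGEZ change
    if (best$type == "acceptor") {
      aw_ref <- substr(ref, max(1L, best$idx - 49L), best$idx + 1L)
      aw_alt <- substr(alt, max(1L, best$idx - 49L), best$idx + 1L)
      p_r <- count_ppt(aw_ref); p_a <- count_ppt(aw_alt)
      if (!is.na(p_a$pyrimidines_in_window) && !is.na(p_r$pyrimidines_in_window) &&
          p_a$pyrimidines_in_window > p_r$pyrimidines_in_window) {
        notes <- c(notes, "PPT strengthened")
      }
      ag_r <- check_agez(aw_ref); ag_a <- check_agez(aw_alt)
      if (isTRUE(ag_a$pass) && identical(ag_r$pass, FALSE)) {
        notes <- c(notes, "AG removed from exclusion zone")
      }
    }
    return(mk(category, best$idx, best$type, best$ref_score, best$alt_score))
  }
  mk("unresolved")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s%s\n", x$category,
              if (!is.na(x$site_pos)) sprintf(" at %d (%s)", x$site_pos,
                                              x$site_type) else ""))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Search for partner splice sites of a created site
#'
#' For a created donor, every upstream AG is considered as a partner
#' acceptor; for a created acceptor, every downstream GT as a partner donor.
#' The implied exon (acceptor boundary to donor boundary, inclusive of both
#' exonic ends) must be 31-750 nt. Each partner is assessed with the
#' splicing checklist items computable in region space (acceptor motif, PPT
#' minimum, AG-exclusion zone; branchpoint absence is indeterminate and does
#' not reject) and retained if it reaches 75% of the model maximum score, or
#' >= 3 bits when within 200 nt of the created site.
#'
#' @param created_site list with `site_index` (1-based index of the created
#'   dinucleotide's first base in `alt_sequence`) and `site_type`
#'   (`"donor"`/`"acceptor"`); typically an [attribute_mechanism()] result.
#' @param alt_sequence sense-strand alternative sequence.
#' @param models list with `donor`/`acceptor` [score_model()]s.
#' @param config a [pseudoexon_config()].
#' @return data.frame of candidates sorted by partner score then proximity:
#'   `acceptor_index`, `donor_index` (first/last exonic base),
#'   `exon_length`, `partner_score`, `checklist_ok`, `strength_75pct`,
#'   `proximity_relaxation`, `retained`.
#' @export
find_partner_sites <- function(created_site, alt_sequence, models = NULL,
                               config = pseudoexon_config()) {
  if (is.null(models)) {
    models <- list(donor = score_model("donor_9mer"),
                   acceptor = score_model("acceptor_23mer"))
  }
  p <- created_site$site_index
  type <- created_site$site_type
  n <- nchar(alt_sequence)
  out <- data.frame(acceptor_index = integer(), donor_index = integer(),
                    exon_length = integer(), partner_score = numeric(),
                    checklist_ok = logical(), strength_75pct = logical(),
                    proximity_relaxation = logical(), retained = logical())
  if (type == "donor") {
    scan <- scan_sites(alt_sequence, "acceptor", models$acceptor)
    mx <- model_max_score(models$acceptor)
  } else {
    scan <- scan_sites(alt_sequence, "donor", models$donor)
    mx <- model_max_score(models$donor)
  }
  for (k in seq_len(nrow(scan))) {
    q <- scan$dinuc_start[k]
    if (type == "donor") {
      acc_i <- q + 2L            # first exonic base after the partner AG
      don_i <- p - 1L            # last exonic base before the created GT
    } else {
      acc_i <- p + 2L            # first exonic base after the created AG
      don_i <- q - 1L            # last exonic base before the partner GT
    }
    len <- don_i - acc_i + 1L
    if (len < config$min_exon_nt || len > config$max_exon_nt) next
    score <- scan$score[k]
    ## checklist items computable in region space for the partner site
    ok <- TRUE
    if (type == "donor") {
      aw <- substr(alt_sequence, max(1L, q - 48L), q + 1L)  # ends at -1 of partner acceptor
      av <- acceptor_motif_verdict(aw)
      ppt <- count_ppt(aw)
      ag <- check_agez(aw)
      checks <- c(av$ok, ppt$passes_minimum, ag$pass)
      ok <- !any(checks %in% FALSE)   # indeterminate does not reject
    } else {
      win9 <- substr(alt_sequence, q - 3L, q + 5L)
      if (nchar(win9) == 9L) {
        dv <- donor_motif_verdict(win9, checklist_config())
        ok <- !identical(dv$ok, FALSE)
      }
    }
    s75 <- !is.na(score) && score >= config$strength_fraction * mx
    relax <- !is.na(score) && len <= config$relax_distance_nt &&
      score >= config$relax_min_score
    retained <- ok && (s75 || relax)
    out <- rbind(out, data.frame(acceptor_index = acc_i, donor_index = don_i,
                                 exon_length = len, partner_score = score,
                                 checklist_ok = ok, strength_75pct = s75,
                                 proximity_relaxation = relax && !s75,
                                 retained = retained))
  }
  out[order(-out$partner_score, out$exon_length), , drop = FALSE]
}

#' Predict pseudoexon creation by a deep intronic variant
#'
#' Composes [attribute_mechanism()] and [find_partner_sites()]: if the
#' variant creates a canonical splice-site dinucleotide (or yields a new /
#' strengthened candidate site), partners are searched on the alternative
#' sequence and the top retained candidate is reported with its predicted
#' inclusion coordinates (genomic).
#'
#' @inheritParams attribute_mechanism
#' @return list with `mechanism`, `candidates` (data.frame, genomic
#'   coordinates added), `top` (one-row data.frame or `NULL`), or
#'   `list(redirect = TRUE)` when the variant lies inside the DD/DA windows.
#' @export
predict_pseudoexon <- function(variant, tm, genome, models = NULL,
                               config = pseudoexon_config()) {
  genome <- as_genome(genome)
  if (nrow(site_windows(tm, variant$pos)) > 0L) {
    return(list(redirect = TRUE,
                message = "variant lies in a splice-site window: use the DD/DA heuristics"))
  }
  mech <- attribute_mechanism(variant, tm, genome, models, config)
  cands <- NULL
  if (mech$category %in% c("created_donor_GT", "created_acceptor_AG",
                           "strengthened_existing_site", "new_candidate_other") &&
      !is.na(mech$site_index)) {
    cands <- find_partner_sites(list(site_index = mech$site_index,
                                     site_type = mech$site_type),
                                mech$alt_seq, models, config)
    if (nrow(cands)) {
      cands$acceptor_pos <- vapply(cands$acceptor_index, function(i)
        region_index_to_genomic(mech$region, i, tm$strand), numeric(1))
      cands$donor_pos <- vapply(cands$donor_index, function(i)
        region_index_to_genomic(mech$region, i, tm$strand), numeric(1))
    }
  }
  top <- NULL
  if (!is.null(cands) && any(cands$retained)) {
    top <- cands[cands$retained, , drop = FALSE][1L, , drop = FALSE]
  }
  list(mechanism = mech, candidates = cands, top = top)
}
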