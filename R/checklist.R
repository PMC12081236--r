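#' Splicing-requirements checklist configuration
#'
#' Defaults encode the minimal requirements for U2 (major-spliceosome)
#' splicing: flanking introns of at least 80 nt, a branchpoint adenosine
#' 17-50 nt upstream of the acceptor, at least nine pyrimidines in the broad
#' polypyrimidine-tract window -24..-5, no AG dinucleotide with its A between
#' -13 and -6 (the AG-exclusion zone; an AG at -5 is tolerated), and exon
#' length minima of 30/31/119 nt for first/internal/last exons. A "strong"
#' PPT has >= 12 consecutive or >= 17 total pyrimidines in -24..-4.
#'
#' The in-silico score thresholds are package defaults (3 bits for either
#' site); they are flagged `insilico_thresholds_default = TRUE` until a user
#' supplies calibrated values.
#'
#' @param ... named overrides of any default field.
#' @return object of class `checklist_config`.
#' @export
checklist_config <- function(...) {
  cfg <- list(
    min_intron_nt = 80L,
    low_risk_bp_to_donor_nt = 60L,
    min_bp_to_donor_nt = 45L,
    bp_window_nt = c(17L, 50L),
    min_exon_nt = list(first = 30L, internal = 31L, last = 119L),
    ppt_window = c(-24L, -5L),
    ppt_min_pyrimidines = 9L,
    strong_ppt = list(consecutive = 12L, total = 17L, window = c(-24L, -4L)),
    agez_window = c(-13L, -6L),
    agez_tolerated = -5L,
    donor_consensus = "CAGGTAAGT",    # E-3..+6, most frequent base per position
    gc_donor_consensus = "CAGGCAAGT", # GC-type donors: C at +2
    gc_donor_min_match = 8L,
    acceptor_consensus = "YAG",       # -3..-1
    branchpoint_motif = "TNA",
    insilico_donor_min = 3,
    insilico_acceptor_min = 3,
    insilico_thresholds_default = TRUE,
    insilico_keep_agez = TRUE,
    insilico_keep_branchpoint = TRUE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown checklist config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "checklist_config")
}

#' Theoretical intron length minima
#'
#' Derived from the spacing constraints alone: the branchpoint must sit at
#' least `bp_window_nt[1]` nt upstream of the acceptor and at least
#' `min_bp_to_donor_nt` nt downstream of the donor (with
#' `low_risk_bp_to_donor_nt` for low mis-splicing risk).
#'
#' @param config a [checklist_config()].
#' @return list with `absolute_min_nt` and `low_risk_min_nt`.
#' @export
theoretical_intron_minimum <- function(config = checklist_config()) {
  list(absolute_min_nt = config$min_bp_to_donor_nt + config$bp_window_nt[1],
       low_risk_min_nt = config$low_risk_bp_to_donor_nt + config$bp_window_nt[1])
}

## Base at relative acceptor position -k of a window whose last char is -1.
acc_base <- function(window, k) {
  n <- nchar(window)
  if (k > n || k < 1L) return(NA_character_)
  substr(window, n - k + 1L, n - k + 1L)
}

#' Polypyrimidine-tract metrics
#'
#' Counts pyrimidines (C/T) in the broad PPT window. The minimum-content
#' check uses -24..-5; the strength check (strong PPT) uses -24..-4 with the
#' thresholds in `config$strong_ppt`.
#'
#' @param acceptor_window sense-strand intronic sequence ending at -1 (i.e.
#'   the last >= 24 nt of the intron).
#' @param config a [checklist_config()].
#' @return list with `pyrimidines_in_window` (count in the minimum window),
#'   `max_consecutive`, `total_in_strength_window`, `is_strong`,
#'   `passes_minimum`. Counts are `NA` when the window does not cover -24 or
#'   contains `N` there.
#' @export
count_ppt <- function(acceptor_window, config = checklist_config()) {
  acceptor_window <- toupper(acceptor_window)
  w_min <- config$ppt_window            # c(-24, -5)
  w_str <- config$strong_ppt$window     # c(-24, -4)
  get_bases <- function(lo, hi) {       # lo/hi negative, lo < hi
    ks <- seq(-lo, -hi)                 # e.g. 24..5
    vapply(ks, function(k) acc_base(acceptor_window, k) %||% NA_character_,
           character(1))
  }
  b_min <- get_bases(w_min[1], w_min[2])
  b_str <- get_bases(w_str[1], w_str[2])
  indet <- anyNA(b_min) || any(b_min == "N") || anyNA(b_str) || any(b_str == "N")
  if (indet) {
    return(list(pyrimidines_in_window = NA_integer_, max_consecutive = NA_integer_,
                total_in_strength_window = NA_integer_, is_strong = NA,
                passes_minimum = NA))
  }
  py_min <- sum(b_min %in% c("C", "T"))
  py_str <- sum(b_str %in% c("C", "T"))
  runs <- rle(b_str %in% c("C", "T"))
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(pyrimidines_in_window = py_min,
       max_consecutive = max_run,
       total_in_strength_window = py_str,
       is_strong = max_run >= config$strong_ppt$consecutive ||
         py_str >= config$strong_ppt$total,
       passes_minimum = py_min >= config$ppt_min_pyrimidines)
}

#' Find branchpoint candidates
#'
#' Scans the acceptor-proximal intron for adenosines matching the configured
#' branchpoint motif (`TNA` by default; `YNA` for the more permissive form)
#' whose distance to the 3'SS falls in the branchpoint window (17-50 nt by
#' default, measured so that the last intronic base is at distance 1).
#'
#' An empty result means "no motif-matching branchpoint found", which the
#' checklist treats as indeterminate, never as failure: the motif captures
#' only a minority fraction of true branchpoints.
#'
#' @param acceptor_region sense-strand intronic sequence ending at -1
#'   (should cover at least -50..-1).
#' @param config a [checklist_config()].
#' @param motif override of `config$branchpoint_motif` (`"TNA"` or `"YNA"`).
#' @return data.frame with `position` (relative, e.g. -25), `distance` (nt to
#'   the 3'SS), `motif` (sequence at -2..0 around the A) and `motif_matched`.
#' @export
find_branchpoints <- function(acceptor_region, config = checklist_config(),
                              motif = NULL) {
  motif <- motif %||% config$branchpoint_motif
  stopifnot(motif %in% c("TNA", "YNA"))
  acceptor_region <- toupper(acceptor_region)
  lohi <- config$bp_window_nt
  out <- data.frame(position = integer(), distance = integer(),
                    motif = character(), motif_matched = character())
  for (d in seq(lohi[1], lohi[2])) {
    a <- acc_base(acceptor_region, d)
    if (is.na(a) || a != "A") next
    t2 <- acc_base(acceptor_region, d + 2L)   # base two upstream of the A
    if (is.na(t2)) next
    hit <- if (motif == "TNA") t2 == "T" else t2 %in% c("C", "T")
    if (!hit) next
    ctx <- paste0(t2, acc_base(acceptor_region, d + 1L), a)
    out <- rbind(out, data.frame(position = -d, distance = d, motif = ctx,
                                 motif_matched = motif))
  }
  out[order(out$distance), , drop = FALSE]
}

#' Check the AG-exclusion zone
#'
#' AG dinucleotides whose A falls between -13 and -6 interfere with
#' 3'SS scanning and are counted as violations; an AG with its A at -5
#' (`AGYAG|G`) is tolerated.
#'
#' @param acceptor_window sense-strand intronic sequence ending at -1.
#' @param config a [checklist_config()].
#' @return list with `violating_AG_positions` (relative positions of the A)
#'   and `pass` (`NA` if the zone contains `N` or is not covered).
#' @export
check_agez <- function(acceptor_window, config = checklist_config()) {
  acceptor_window <- toupper(acceptor_window)
  zone <- config$agez_window   # c(-13, -6)
  viol <- integer()
  indet <- FALSE
  for (d in seq(-zone[1], -zone[2])) {  # 13..6
    a <- acc_base(acceptor_window, d)
    g <- acc_base(acceptor_window, d - 1L)
    if (is.na(a) || is.na(g) || a == "N" || g == "N") { indet <- TRUE; next }
    if (a == "A" && g == "G") viol <- c(viol, -d)
  }
  if (length(viol) == 0L && indet) {
    return(list(violating_AG_positions = integer(), pass = NA))
  }
  list(violating_AG_positions = viol, pass = length(viol) == 0L)
}

## Manual donor-motif verdict on the 9-mer E-3..+6. GC donors are accepted
## only when the remainder matches the GC-specific consensus well enough.
donor_motif_verdict <- function(window9, config) {
  b <- chars(window9)
  if (any(b == "N")) return(list(ok = NA, gc_donor = NA, measured = window9))
  dinuc <- paste0(b[4], b[5])
  if (dinuc == "GT") return(list(ok = TRUE, gc_donor = FALSE, measured = window9))
  if (dinuc == "GC") {
    cons <- chars(config$gc_donor_consensus)
    nmatch <- sum(b == cons)
    return(list(ok = nmatch >= config$gc_donor_min_match, gc_donor = TRUE,
                measured = sprintf("%s (GC donor, %d/9 consensus)", window9, nmatch)))
  }
  list(ok = FALSE, gc_donor = FALSE, measured = window9)
}

## Manual acceptor-motif verdict: requires Y at -3, A at -2, G at -1.
acceptor_motif_verdict <- function(acceptor_window) {
  b3 <- acc_base(acceptor_window, 3L); b2 <- acc_base(acceptor_window, 2L)
  b1 <- acc_base(acceptor_window, 1L)
  bs <- c(b3, b2, b1)
  if (anyNA(bs) || any(bs == "N")) return(list(ok = NA, measured = paste(bs, collapse = "")))
  list(ok = b3 %in% c("C", "T") && b2 == "A" && b1 == "G",
       measured = paste0(b3, b2, b1))
}

#' Evaluate the splicing-requirements checklist for an exon
#'
#' Applies every checklist item to a candidate exon: flanking intron lengths,
#' exon length, donor and acceptor motifs (manual mode) or site-strength
#' thresholds (in-silico mode), polypyrimidine-tract content, AG-exclusion
#' zone, and branchpoint presence. First and last exons skip the absent
#' flank. A missing branchpoint is reported `indeterminate`, never `fail`,
#' and does not gate the overall verdict. Any predicate touching an `N` base
#' is `indeterminate`.
#'
#' @param tm a [transcript_model()].
#' @param exon_index exon number in transcript orientation.
#' @param genome genome (named character vector, `DNAStringSet`, FASTA path).
#' @param config a [checklist_config()].
#' @param mode `"manual"` (motif checks) or `"in_silico"` (score thresholds).
#' @param model_donor,model_acceptor scoring models for in-silico mode.
#' @return object of class `checklist_result`: list of itemized verdicts and
#'   an `overall` verdict. Extra non-gating PPT metrics are reported under
#'   `$metrics`.
#' @export
evaluate_checklist <- function(tm, exon_index, genome,
                               config = checklist_config(),
                               mode = c("manual", "in_silico"),
                               model_donor = NULL, model_acceptor = NULL) {
  mode <- match.arg(mode)
  genome <- as_genome(genome)
  n <- n_exons(tm)
  stopifnot(exon_index >= 1L, exon_index <= n)
  cat_i <- exon_category(tm, exon_index)
  items <- list()
  add <- function(name, ok, measured) {
    items[[name]] <<- list(verdict = verdict(ok), measured = measured)
  }
  metrics <- list()

  L <- exon_length(tm, exon_index)
  min_L <- config$min_exon_nt[[cat_i]]
  add("exon_length", L >= min_L, sprintf("%d nt (%s exon, min %d)", L, cat_i, min_L))

  ins <- introns(tm)
  has_up <- exon_index > 1L      # upstream intron -> acceptor side of exon
  has_dn <- exon_index < n       # downstream intron -> donor side of exon

  if (mode == "in_silico") {
    if (is.null(model_donor)) model_donor <- score_model("donor_9mer")
    if (is.null(model_acceptor)) model_acceptor <- score_model("acceptor_23mer")
    if (isTRUE(config$insilico_thresholds_default)) {
      message("in-silico checklist thresholds are package defaults; ",
              "supply calibrated insilico_donor_min/insilico_acceptor_min ",
              "for production use")
    }
  }

  if (has_dn) {
    j <- exon_index                   # donor of intron j
    M <- ins$length[j]
    add("intron_length_downstream", M >= config$min_intron_nt,
        sprintf("%d nt (min %d)", M, config$min_intron_nt))
    ctx <- extract_splice_context(tm, j, genome, exonic_n = min(50L, L))
    win9 <- paste0(substr(ctx$donor_exonic, nchar(ctx$donor_exonic) - 2L,
                          nchar(ctx$donor_exonic)),
                   substr(ctx$donor_intronic, 1L, 6L))
    if (mode == "manual") {
      dv <- donor_motif_verdict(win9, config)
      add("donor_motif", dv$ok, dv$measured)
      metrics$gc_donor <- dv$gc_donor
    } else {
      sc <- score_donor(win9, model_donor)$value
      add("donor_motif", if (is.na(sc)) NA else sc >= config$insilico_donor_min,
          sprintf("%.2f bits (min %.2f)", sc, config$insilico_donor_min))
    }
  }

  if (has_up) {
    j <- exon_index - 1L              # acceptor of intron j
    M <- ins$length[j]
    add("intron_length_upstream", M >= config$min_intron_nt,
        sprintf("%d nt (min %d)", M, config$min_intron_nt))
    ctx <- extract_splice_context(tm, j, genome,
                                  exonic_n = min(50L, L),
                                  acceptor_intronic_n = min(50L, M))
    aw <- ctx$acceptor_intronic
    if (mode == "manual") {
      av <- acceptor_motif_verdict(aw)
      add("acceptor_motif", av$ok, av$measured)
    } else {
      win23 <- paste0(substr(aw, nchar(aw) - 19L, nchar(aw)),
                      substr(ctx$acceptor_exonic, 1L, 3L))
      sc <- if (nchar(win23) == 23L) score_acceptor(win23, model_acceptor)$value else NA_real_
      add("acceptor_motif", if (is.na(sc)) NA else sc >= config$insilico_acceptor_min,
          sprintf("%.2f bits (min %.2f)", sc, config$insilico_acceptor_min))
    }
    ppt <- count_ppt(aw, config)
    add("ppt", ppt$passes_minimum,
        sprintf("%s pyrimidines in %d..%d (min %d)",
                ppt$pyrimidines_in_window, config$ppt_window[1],
                config$ppt_window[2], config$ppt_min_pyrimidines))
    metrics$ppt <- ppt
    do_agez <- mode == "manual" || isTRUE(config$insilico_keep_agez)
    if (do_agez) {
      ag <- check_agez(aw, config)
      add("agez", ag$pass,
          if (length(ag$violating_AG_positions))
            paste("AG at", paste(ag$violating_AG_positions, collapse = ","))
          else "no AG in exclusion zone")
    }
    do_bp <- mode == "manual" || isTRUE(config$insilico_keep_branchpoint)
    if (do_bp) {
      bps <- find_branchpoints(aw, config)
      ## absence of a motif match is indeterminate, not fail
      add("branchpoint", if (nrow(bps) > 0L) TRUE else NA,
          sprintf("%d %s candidate(s) in %d..%d nt", nrow(bps),
                  config$branchpoint_motif, config$bp_window_nt[1],
                  config$bp_window_nt[2]))
      metrics$branchpoints <- bps
    }
  }

  verdicts <- vapply(items, `[[`, character(1), "verdict")
  gating <- verdicts[setdiff(names(verdicts), "branchpoint")]
  overall <- if (any(gating == "fail")) "fail"
  else if (any(gating == "indeterminate")) "indeterminate"
  else "pass"
  structure(list(transcript_id = tm$transcript_id, exon_index = exon_index,
                 exon_category = cat_i, mode = mode, items = items,
                 metrics = metrics, overall = overall),
            class = "checklist_result")
}

#' @export
print.checklist_result <- function(x, ...) {
  cat(sprintf("<checklist_result> %s exon %d (%s, %s mode): %s\n",
              x$transcript_id, x$exon_index, x$exon_category, x$mode,
              toupper(x$overall)))
  for (nm in names(x$items)) {
    it <- x$items[[nm]]
    cat(sprintf("  %-26s %-13s %s\n", nm, it$verdict, it$measured))
  }
  invisible(x)
}
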