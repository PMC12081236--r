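## Re-estimation of spliceogenicity, subgroup validity checks, and
## splicing-outcome aggregation from labeled variant evidence tables.

OUTCOME_VOCABULARY <- c("exon_skipping", "exon_truncation", "exon_extension",
                        "intron_retention", "pseudoexon_inclusion")

#' Load a labeled variant evidence table
#'
#' Tab-separated dialect with columns `chrom, pos, ref, alt, genome_build,
#' classification, outcomes, method`. Only high-confidence rows labeled
#' `splice-altering` or `normal` are kept; rows with intermediate labels
#' (e.g. low-frequency splicing) are dropped at load, or rejected when
#' `strict = TRUE`. `outcomes` is a comma-separated subset of the outcome
#' vocabulary; an empty field on a splice-altering row means "outcome not
#' reported" and the sentinel `none` means "reported, no specific outcome".
#'
#' @param path TSV file.
#' @param strict error on unknown classification labels instead of dropping.
#' @return data.frame of class `labeled_variant_table`; `outcomes` is a list
#'   column of character vectors (`NA` when not reported).
#' @export
load_evidence_table <- function(path, strict = FALSE) {
  tab <- as.data.frame(data.table::fread(path, colClasses = list(character = "outcomes")))
  need <- c("chrom", "pos", "ref", "alt", "classification")
  if (!all(need %in% names(tab))) {
    stop("evidence table must have columns: ", paste(need, collapse = ", "))
  }
  known <- tab$classification %in% c("splice-altering", "normal")
  if (!all(known)) {
    if (strict) {
      stop("unknown classification label(s): ",
           paste(unique(tab$classification[!known]), collapse = ", "))
    }
    message(sprintf("dropping %d row(s) with non-binary labels", sum(!known)))
    tab <- tab[known, , drop = FALSE]
  }
  if (!"outcomes" %in% names(tab)) tab$outcomes <- NA_character_
  parse_outcomes <- function(s) {
    if (is.na(s) || s == "") return(NA_character_)
    if (s == "none") return(character(0))
    oo <- strsplit(s, ",", fixed = TRUE)[[1]]
    bad <- setdiff(oo, OUTCOME_VOCABULARY)
    if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "))
    oo
  }
  tab$outcomes <- lapply(tab$outcomes, parse_outcomes)
  class(tab) <- c("labeled_variant_table", class(tab))
  tab
}

#' Wald binomial confidence interval (percent scale)
#'
#' Normal-approximation interval `p +/- 1.96 sqrt(p(1-p)/n)`, clamped to
#' [0, 100]. This is the interval form closest to published subgroup
#' annotations; bundled values are stored verbatim and never recomputed.
#'
#' @param k successes.
#' @param n trials.
#' @param z normal quantile (1.96 for a 95% interval).
#' @return list with `p`, `ci` (length-2, percent).
#' @export
wald_ci <- function(k, n, z = 1.96) {
  stopifnot(n > 0, k >= 0, k <= n)
  phat <- k / n
  half <- z * sqrt(phat * (1 - phat) / n)
  list(p = 100 * phat,
       ci = c(max(0, 100 * (phat - half)), min(100, 100 * (phat + half))))
}

#' Estimate spliceogenicity per heuristic subgroup
#'
#' Spliceogenicity is the proportion of variants in a subgroup confirmed to
#' be splice-altering. Estimates are `user_estimate`s; they never overwrite
#' the bundled annotations. Rows classified into U12 introns are excluded.
#'
#' @param table a [load_evidence_table()] result (or data.frame with a
#'   `classification` column).
#' @param grouping character vector (one per row) of subgroup keys, e.g.
#'   `"DD2 standard"`, or a list of `subgroup_assignment`s; `NA` /
#'   unassigned rows are dropped.
#' @return data.frame: `subgroup`, `k`, `n`, `p`, `ci_low`, `ci_high`,
#'   `source`. Empty subgroups are omitted (with a diagnostic via message).
#' @export
estimate_spliceogenicity <- function(table, grouping) {
  if (is.list(grouping) && length(grouping) && inherits(grouping[[1]], "subgroup_assignment")) {
    grouping <- vapply(grouping, function(a) {
      if (is.na(a$rule_id) || "U12_unsupported" %in% a$flags) NA_character_
      else paste(a$rule_id, a$subgroup)
    }, character(1))
  }
  stopifnot(length(grouping) == nrow(table))
  keep <- !is.na(grouping)
  if (any(!keep)) {
    message(sprintf("%d unassigned/U12 row(s) excluded from estimation",
                    sum(!keep)))
  }
  tab <- table[keep, , drop = FALSE]
  grouping <- grouping[keep]
  out <- NULL
  for (g in unique(grouping)) {
    rows <- tab[grouping == g, , drop = FALSE]
    n <- nrow(rows)
    k <- sum(rows$classification == "splice-altering")
    w <- wald_ci(k, n)
    out <- rbind(out, data.frame(subgroup = g, k = k, n = n, p = w$p,
                                 ci_low = w$ci[1], ci_high = w$ci[2],
                                 source = "user_estimate"))
  }
  out[order(out$subgroup), , drop = FALSE]
}

#' Validate subgroup estimates against the inclusion rules
#'
#' Flags subgroups supported by fewer than 10 variants (insufficient
#' evidence) and contextual-modifier subgroups separated from their
#' standard subgroup by less than 15 percentage points of spliceogenicity.
#'
#' @param estimates an [estimate_spliceogenicity()] result; `subgroup` keys
#'   must look like `"<rule_id> <subgroup>"`.
#' @param min_n,min_separation the inclusion thresholds.
#' @return data.frame with `subgroup`, `insufficient_n`, `low_separation`.
#' @export
validate_subgroups <- function(estimates, min_n = 10L, min_separation = 15) {
  parts <- strsplit(estimates$subgroup, " ", fixed = TRUE)
  rule <- vapply(parts, `[`, character(1), 1L)
  sub <- vapply(parts, `[`, character(1), 2L)
  low_sep <- rep(FALSE, nrow(estimates))
  for (i in which(sub == "context")) {
    j <- which(rule == rule[i] & sub == "standard")
    if (length(j) == 1L) {
      low_sep[i] <- abs(estimates$p[i] - estimates$p[j]) < min_separation
    }
  }
  data.frame(subgroup = estimates$subgroup,
             insufficient_n = estimates$n < min_n,
             low_separation = low_sep)
}

#' Map a site-relative label to its splicing region
#'
#' Regions follow the outcome-reporting windows: the donor site (E-3..+6),
#' the acceptor motif (-6..E+1), the polypyrimidine tract (-7..-24) and the
#' branchpoint region (-25..-50).
#'
#' @param label site-relative label.
#' @param site_class `"donor"` or `"acceptor"`.
#' @return region name.
#' @export
splice_region <- function(label, site_class) {
  if (site_class == "donor") return("donor_site")
  k <- label_kind(label)
  if (k == "E+") return("acceptor_motif")
  d <- label_offset(label)
  if (d <= 6L) "acceptor_motif" else if (d <= 24L) "ppt" else "branchpoint_region"
}

#' Aggregate splicing outcomes per region
#'
#' Multi-label percentages: each outcome's percentage is the share of
#' outcome-reporting SAVs listing it, so percentages can sum past 100. A
#' region's profile is `reportable` only when more than 20 SAVs had their
#' transcript impact reported. The denominator counts variants with outcome
#' information (including `none`), each once.
#'
#' @param table a [load_evidence_table()] result restricted to SAVs (rows
#'   labeled `normal` are ignored with a message).
#' @param grouping character vector of region names, one per row.
#' @param min_reported reporting threshold (default 20: profiles need
#'   `n_reported > 20`).
#' @return named list of region profiles, each with `percentages`,
#'   `n_reported`, `multi_outcome_rate`, `reportable`.
#' @export
aggregate_outcomes <- function(table, grouping, min_reported = 20L) {
  stopifnot(length(grouping) == nrow(table))
  sav <- table$classification == "splice-altering"
  if (any(!sav)) {
    message(sprintf("ignoring %d non-SAV row(s) for outcome aggregation",
                    sum(!sav)))
  }
  tab <- table[sav, , drop = FALSE]
  grouping <- grouping[sav]
  out <- list()
  for (g in unique(grouping[!is.na(grouping)])) {
    rows <- tab[!is.na(grouping) & grouping == g, , drop = FALSE]
    reported <- !vapply(rows$outcomes, function(o) length(o) == 1L && is.na(o[1]),
                        logical(1))
    oo <- rows$outcomes[reported]
    n_rep <- length(oo)
    pct <- vapply(OUTCOME_VOCABULARY, function(v) {
      if (n_rep == 0L) return(NA_real_)
      100 * sum(vapply(oo, function(x) v %in% x, logical(1))) / n_rep
    }, numeric(1))
    multi <- if (n_rep == 0L) NA_real_ else
      sum(vapply(oo, length, integer(1)) >= 2L) / n_rep
    out[[g]] <- list(percentages = pct, n_reported = n_rep,
                     multi_outcome_rate = multi,
                     reportable = n_rep > min_reported)
  }
  out
}
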