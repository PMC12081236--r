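## Rule-table loading and validation. The decision trees ship as a versioned
## JSON data file so the classification engine itself stays data-driven and
## testable with alternative tables.

PREDICATE_VOCABULARY <- c(
  "ref_base_is", "alt_base_is", "creates_dinucleotide",
  "destroys_dinucleotide", "cascade_compare", "context_base",
  "ppt_is_strong", "bp_proximity", "bp_destroyed",
  "motif_match_count", "gc_donor", "gt_donor"
)

## Expand a list of {from,to} label ranges into an explicit label vector.
expand_positions <- function(ranges) {
  unlist(lapply(ranges, function(r) {
    kf <- label_kind(r$from); kt <- label_kind(r$to)
    if (kf != kt) stop("position range spans label kinds: ", r$from, "..", r$to)
    paste0(kf, seq(label_offset(r$from), label_offset(r$to)))
  }))
}

#' Load and validate a heuristic rule table
#'
#' Reads the decision-tree data file (bundled by default), validates every
#' predicate against the engine vocabulary, checks that every assignment has
#' a spliceogenicity annotation supported by at least 10 variants, and
#' expands position ranges.
#'
#' @param path JSON rule file; defaults to the bundled table.
#' @return object of class `rule_table` with `annotations` (data.frame),
#'   `paths` (per site class, positions expanded), `cascades` and
#'   `outcome_profiles`.
#' @export
load_rule_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "heuristic_rules.json",
                        package = "heurosplice", mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ann <- do.call(rbind, lapply(raw$annotations, function(a) {
    data.frame(rule_id = a$rule_id, subgroup = a$subgroup, p = a$p,
               ci_low = a$ci[[1]], ci_high = a$ci[[2]], n = a$n,
               source = a$source)
  }))
  ## the >= 10 supporting-variants inclusion rule
  bad_n <- ann$n < 10
  if (any(bad_n)) {
    stop("annotation(s) with n < 10 violate the 10-variant inclusion rule: ",
         paste(ann$rule_id[bad_n], ann$subgroup[bad_n], collapse = "; "))
  }
  if (any(ann$ci_low > ann$p | ann$p > ann$ci_high)) {
    stop("annotation with p outside its confidence interval")
  }
  if (!all(ann$subgroup %in% c("standard", "context", "auxiliary"))) {
    stop("subgroup must be standard/context/auxiliary")
  }
  key <- paste(ann$rule_id, ann$subgroup)
  paths <- lapply(raw$paths, function(site_paths) {
    lapply(site_paths, function(p) {
      labels <- expand_positions(p$positions)
      for (br in p$branches) {
        for (pr in br$when) {
          if (!pr$pred %in% PREDICATE_VOCABULARY) {
            stop("unknown predicate: ", pr$pred)
          }
          if (pr$pred == "context_base" && is.null(pr$at)) {
            stop("context_base predicate must declare its context position")
          }
          if (pr$pred == "cascade_compare" &&
              !pr$cascade %in% names(raw$cascades)) {
            stop("cascade_compare references undeclared cascade: ", pr$cascade)
          }
        }
        akey <- paste(br$assign[[1]], br$assign[[2]])
        if (!akey %in% key) stop("assignment without annotation: ", akey)
      }
      list(labels = labels, branches = p$branches)
    })
  })
  cascades <- lapply(raw$cascades, function(cc) unlist(cc))
  for (cc in cascades) {
    if (!setequal(names(cc), c("A", "C", "G", "T"))) {
      stop("cascade must rank all four bases")
    }
  }
  structure(list(version = raw$version, annotations = ann, paths = paths,
                 cascades = cascades,
                 outcome_profiles = raw$outcome_profiles),
            class = "rule_table")
}

#' @export
print.rule_table <- function(x, ...) {
  cat(sprintf("<rule_table> v%s: %d annotated subgroups over %d rules\n",
              x$version, nrow(x$annotations),
              length(unique(x$annotations$rule_id))))
  invisible(x)
}

## Annotation lookup for one rule/subgroup.
rule_annotation <- function(rule_table, rule_id, subgroup) {
  a <- rule_table$annotations
  row <- a[a$rule_id == rule_id & a$subgroup == subgroup, , drop = FALSE]
  if (nrow(row) != 1L) stop("no annotation for ", rule_id, " ", subgroup)
  list(p = row$p, ci = c(row$ci_low, row$ci_high), n = row$n,
       source = row$source)
}

#' Route a relative position to its applicable heuristics
#'
#' @param label a site-relative position label (e.g. `"+5"`, `"E-1"`,
#'   `"-10"`) or a [relative_position()].
#' @param site_class `"donor"` or `"acceptor"`.
#' @param rule_table a [load_rule_table()] result.
#' @return character vector of rule ids in flowchart evaluation order; empty
#'   with `attr(, "signal")` `"not_covered"` when the position lies outside
#'   every heuristic window (deep intronic / exonic: use the pseudoexon or
#'   SRE pathway).
#' @export
route <- function(label, site_class = c("donor", "acceptor"),
                  rule_table = load_rule_table()) {
  site_class <- match.arg(site_class)
  if (inherits(label, "relative_position")) label <- format_relpos(label)
  for (p in rule_table$paths[[site_class]]) {
    if (label %in% p$labels) {
      ids <- unique(vapply(p$branches, function(b) b$assign[[1]], character(1)))
      return(ids)
    }
  }
  out <- character(0)
  attr(out, "signal") <- "not_covered"
  out
}
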