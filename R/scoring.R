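## Splice-site strength scoring.
##
## Two model kinds share one interface:
##  * pwm_first_order - a first-order position-weight log-odds model built
##    from bundled per-position base frequencies (no downloads needed).
##  * maxent          - the published maximum-entropy scheme, available when
##    a directory of standard score-matrix files is supplied (see maxent.R).
##
## Scores are log2-odds in bits against a uniform background. The donor
## window is exactly 9 nt (E-3..+6); the acceptor window is exactly 23 nt
## (-20..E+3).

DONOR_WIDTH <- 9L
ACCEPTOR_WIDTH <- 23L

#' Build a first-order position-weight scoring model
#'
#' @param site_type `"donor_9mer"` or `"acceptor_23mer"`.
#' @param frequencies optional numeric matrix (positions x `A,C,G,T`) of base
#'   frequencies; defaults to the tables bundled with the package. Rows must
#'   sum to 1 (a small tolerance is allowed).
#' @param background length-4 background distribution (default uniform).
#' @return object of class `score_model`.
#' @export
score_model <- function(site_type = c("donor_9mer", "acceptor_23mer"),
                        frequencies = NULL,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  site_type <- match.arg(site_type)
  width <- if (site_type == "donor_9mer") DONOR_WIDTH else ACCEPTOR_WIDTH
  if (is.null(frequencies)) {
    fn <- if (site_type == "donor_9mer") "donor_frequencies.tsv" else "acceptor_frequencies.tsv"
    path <- system.file("extdata", fn, package = "heurosplice", mustWork = TRUE)
    tab <- as.data.frame(data.table::fread(path))
    frequencies <- as.matrix(tab[, c("A", "C", "G", "T")])
    rownames(frequencies) <- tab$position
  }
  if (nrow(frequencies) != width) {
    stop(sprintf("%s model needs %d positions, got %d", site_type, width,
                 nrow(frequencies)))
  }
  if (any(abs(rowSums(frequencies) - 1) > 1e-3)) {
    stop("frequency rows must sum to 1")
  }
  if (any(frequencies <= 0)) stop("frequencies must be strictly positive")
  lo <- log2(sweep(frequencies, 2, background[colnames(frequencies)], "/"))
  structure(list(model_kind = "pwm_first_order", site_type = site_type,
                 frequencies = frequencies, background = background,
                 log_odds = lo, width = width),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model> %s / %s (%d nt window)\n", x$model_kind,
              x$site_type, x$width))
  invisible(x)
}

## Internal dispatcher shared by score_donor / score_acceptor.
score_window <- function(window, model, site_type) {
  stopifnot(inherits(model, "score_model"))
  if (model$site_type != site_type) {
    stop(sprintf("model is for %s, not %s", model$site_type, site_type))
  }
  window <- toupper(window)
  if (nchar(window) != model$width) {
    stop(sprintf("window must be exactly %d nt, got %d", model$width,
                 nchar(window)))
  }
  b <- chars(window)
  if (any(!b %in% c("A", "C", "G", "T"))) {
    return(site_score(NA_real_, site_type, model$model_kind))
  }
  value <- if (model$model_kind == "pwm_first_order") {
    sum(model$log_odds[cbind(seq_along(b), match(b, colnames(model$log_odds)))])
  } else {
    maxent_score(window, model)
  }
  site_score(value, site_type, model$model_kind)
}

site_score <- function(value, site_type, model_kind, position = NA) {
  structure(list(value = value, site_type = site_type,
                 model_kind = model_kind, position = position),
            class = "site_score")
}

#' @export
print.site_score <- function(x, ...) {
  cat(sprintf("<site_score> %s %.4f bits (%s)\n", x$site_type,
              x$value, x$model_kind))
  invisible(x)
}

#' Score a donor (5'SS) window
#'
#' The 9-mer spans E-3..+6 (last three exonic bases, first six intronic).
#' Windows containing any base outside A/C/G/T score `NA` (indeterminate).
#'
#' @param window 9 nt character string.
#' @param model a [score_model()] (or maxent model) with
#'   `site_type = "donor_9mer"`.
#' @return a `site_score` whose `$value` is the log2-odds score in bits.
#' @export
score_donor <- function(window, model = score_model("donor_9mer")) {
  score_window(window, model, "donor_9mer")
}

#' Score an acceptor (3'SS) window
#'
#' The 23-mer spans -20..E+3 (twenty intronic bases ending in the invariant
#' AG, then the first three exonic bases).
#'
#' @inheritParams score_donor
#' @export
score_acceptor <- function(window, model = score_model("acceptor_23mer")) {
  score_window(window, model, "acceptor_23mer")
}

#' Maximum achievable score of a model
#'
#' Computed exactly: per-position maximization for the factorized PWM model,
#' and dynamic programming over the maximum-entropy factorization for maxent
#' models (never by sampling).
#'
#' @param model a [score_model()].
#' @return maximum score in bits.
#' @export
model_max_score <- function(model) {
  stopifnot(inherits(model, "score_model"))
  if (model$model_kind == "pwm_first_order") {
    sum(apply(model$log_odds, 1, max))
  } else {
    maxent_max_score(model)
  }
}

#' Combined splice-site strength across an intron
#'
#' @param donor,acceptor `site_score`s from the same model kind.
#' @return sum of the two scores in bits.
#' @export
combined_intron_strength <- function(donor, acceptor) {
  stopifnot(inherits(donor, "site_score"), inherits(acceptor, "site_score"))
  if (!identical(donor$model_kind, acceptor$model_kind)) {
    stop("donor and acceptor scores come from different model kinds")
  }
  donor$value + acceptor$value
}

#' Scan a region for candidate splice sites
#'
#' Scores every GT dinucleotide (donor scan) or AG dinucleotide (acceptor
#' scan) in a sense-strand region whose full scoring window fits inside the
#' region. Positions are reported at the exon/intron boundary convention of
#' the site type: `boundary` is the 1-based index, within `region`, of the
#' last exonic base of the implied exon (donor: the base before the G of GT;
#' acceptor: `boundary` is the first exonic base following AG).
#'
#' @param region sense-strand sequence.
#' @param site_type `"donor"` or `"acceptor"`.
#' @param model matching [score_model()].
#' @return data.frame with `dinuc_start` (index of G of GT / A of AG),
#'   `boundary`, `score`; zero rows when nothing matches.
#' @export
scan_sites <- function(region, site_type = c("donor", "acceptor"),
                       model = NULL) {
  site_type <- match.arg(site_type)
  region <- toupper(region)
  if (is.null(model)) {
    model <- score_model(if (site_type == "donor") "donor_9mer" else "acceptor_23mer")
  }
  pat <- if (site_type == "donor") "GT" else "AG"
  hits <- gregexpr(paste0("(?=", pat, ")"), region, perl = TRUE)[[1]]
  empty <- data.frame(dinuc_start = integer(), boundary = integer(),
                      score = numeric())
  if (hits[1] == -1L) return(empty)
  out <- empty
  n <- nchar(region)
  for (p in as.integer(hits)) {
    if (site_type == "donor") {
      ## window E-3..+6: starts 3 nt before the G of GT
      ws <- p - 3L; we <- p + 5L
      if (ws < 1L || we > n) next
      sc <- score_donor(substr(region, ws, we), model)
      out <- rbind(out, data.frame(dinuc_start = p, boundary = p - 1L,
                                   score = sc$value))
    } else {
      ## window -20..E+3: AG occupies positions 19-20 of the 23-mer
      ws <- p - 18L; we <- p + 4L
      if (ws < 1L || we > n) next
      sc <- score_acceptor(substr(region, ws, we), model)
      out <- rbind(out, data.frame(dinuc_start = p, boundary = p + 2L,
                                   score = sc$value))
    }
  }
  out
}
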