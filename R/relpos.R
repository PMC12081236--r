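#' Relative splice-position nomenclature
#'
#' Positions are anchored to the nearest exon-intron boundary using an
#' HGVS-like scheme: `+k` is the k-th base of an intron counting from its 5'
#' (donor) end, `-k` the k-th base counting back from its 3' (acceptor) end,
#' `E+k` the k-th base of an exon from its 5' start and `E-k` the k-th base
#' from its 3' end. The first base of an exon is `E+1`, the penultimate base
#' is `E-2`, the third intronic base after a donor is `+3`.
#'
#' @param kind one of `"+"`, `"-"`, `"E+"`, `"E-"`.
#' @param offset integer >= 1.
#' @param exon_index exon (for `E+`/`E-`) or intron (for `+`/`-`) index in
#'   transcript orientation.
#' @param exon_category `"first"`, `"internal"`, `"last"` or `NA`.
#' @return object of class `relative_position`.
#' @export
relative_position <- function(kind, offset, exon_index = NA_integer_,
                              exon_category = NA_character_) {
  stopifnot(kind %in% c("+", "-", "E+", "E-"), offset >= 1L)
  structure(list(kind = kind, offset = as.integer(offset),
                 exon_index = as.integer(exon_index),
                 exon_category = exon_category),
            class = "relative_position")
}

#' @rdname relative_position
#' @param x a `relative_position` (or its string form for `parse_relpos`).
#' @export
format_relpos <- function(x) {
  if (inherits(x, "relative_position")) return(paste0(x$kind, x$offset))
  as.character(x)
}

#' @export
format.relative_position <- function(x, ...) format_relpos(x)

#' @export
print.relative_position <- function(x, ...) {
  cat(sprintf("<relative_position> %s (exon/intron %s, %s)\n", format_relpos(x),
              x$exon_index, x$exon_category))
  invisible(x)
}

#' @rdname relative_position
#' @export
parse_relpos <- function(x) {
  m <- regmatches(x, regexec("^(E[+-]|[+-])([0-9]+)$", x))[[1]]
  if (length(m) != 3L) stop("unparseable relative position: ", x)
  relative_position(m[2], as.integer(m[3]))
}

## Label arithmetic: split "+5"/"-13"/"E+1"/"E-2" into kind/offset quickly.
label_kind <- function(label) sub("^(E[+-]|[+-]).*$", "\\1", label)
label_offset <- function(label) as.integer(sub("^(E[+-]|[+-])", "", label))

#' Map a genomic position to its relative splice position
#'
#' Intronic positions within the 5' half of an intron (ties at an even-length
#' midpoint included) are reported as `+k` from the upstream donor; the rest
#' as `-k` from the downstream acceptor. Exonic positions carry both `E+k`
#' and `E-k`; the smaller offset is primary (ties resolve to `E+`).
#'
#' @param pos 1-based genomic position.
#' @param tm a [transcript_model()].
#' @return a `relative_position` (with a `secondary` attribute for exonic
#'   positions), or `NULL` with an "intergenic" message if `pos` lies outside
#'   the transcript span.
#' @export
map_to_relative <- function(pos, tm) {
  loc <- locate_position(pos, tm)
  if (is.null(loc)) {
    message(sprintf("position %s:%d is intergenic for %s", tm$chrom, pos,
                    tm$transcript_id))
    return(NULL)
  }
  if (loc$where == "exon") {
    i <- loc$index; L <- exon_length(tm, i)
    k <- loc$offset5               # 1-based from exon 5' start
    m <- L - k + 1L                # from exon 3' end
    cat_i <- exon_category(tm, i)
    fwd <- relative_position("E+", k, i, cat_i)
    rev <- relative_position("E-", m, i, cat_i)
    if (m < k) { primary <- rev; secondary <- fwd } else { primary <- fwd; secondary <- rev }
    attr(primary, "secondary") <- secondary
    primary
  } else {
    j <- loc$index; M <- loc$length; d <- loc$offset5
    if (d <= ceiling(M / 2)) {
      relative_position("+", d, j, NA_character_)
    } else {
      relative_position("-", M - d + 1L, j, NA_character_)
    }
  }
}

## Locate a 1-based genomic position in a transcript.
## Returns list(where = "exon"/"intron", index, offset5 = 1-based offset from
## the feature's 5' end in transcript orientation, length) or NULL.
locate_position <- function(pos, tm) {
  p0 <- pos - 1L   # 0-based
  for (i in seq_len(n_exons(tm))) {
    s <- tm$exons$start[i]; e <- tm$exons$end[i]
    if (p0 >= s && p0 < e) {
      off <- if (tm$strand == "+") p0 - s + 1L else e - p0
      return(list(where = "exon", index = i, offset5 = off, length = e - s))
    }
  }
  ins <- introns(tm)
  for (j in seq_len(nrow(ins))) {
    s <- ins$start[j]; e <- ins$end[j]
    if (p0 >= s && p0 < e) {
      off <- if (tm$strand == "+") p0 - s + 1L else e - p0
      return(list(where = "intron", index = j, offset5 = off, length = e - s))
    }
  }
  NULL
}

## 1-based genomic position of a site-relative label.
## site_class "donor": labels E-k (exon j) and +k (intron j).
## site_class "acceptor": labels -k (intron j) and E+k (exon j+1).
rel_to_genomic <- function(tm, intron_index, site_class, label) {
  kind <- label_kind(label); k <- label_offset(label)
  ins <- introns(tm)
  stopifnot(intron_index >= 1L, intron_index <= nrow(ins))
  plus <- tm$strand == "+"
  if (site_class == "donor") {
    if (kind == "E-") {
      i <- intron_index
      if (plus) tm$exons$end[i] - k + 1L else tm$exons$start[i] + k
    } else if (kind == "+") {
      if (plus) ins$start[intron_index] + k else ins$end[intron_index] - k + 1L
    } else stop("label ", label, " not in donor window")
  } else if (site_class == "acceptor") {
    if (kind == "-") {
      if (plus) ins$end[intron_index] - k + 1L else ins$start[intron_index] + k
    } else if (kind == "E+") {
      i <- intron_index + 1L
      if (plus) tm$exons$start[i] + k else tm$exons$end[i] - k + 1L
    } else stop("label ", label, " not in acceptor window")
  } else stop("site_class must be donor or acceptor")
}

## All heuristic-window mappings of a genomic position: data.frame with
## site_class, intron_index, label. Donor window is E-3..+6; acceptor window
## is -50..E+1. A position can fall in both windows (short introns/exons).
site_windows <- function(tm, pos, donor_exonic = 3L, donor_intronic = 6L,
                         acceptor_intronic = 50L, acceptor_exonic = 1L) {
  loc <- locate_position(pos, tm)
  out <- data.frame(site_class = character(), intron_index = integer(),
                    label = character())
  if (is.null(loc)) return(out)
  n <- n_exons(tm)
  if (loc$where == "exon") {
    i <- loc$index; L <- loc$length
    m <- L - loc$offset5 + 1L
    if (m <= donor_exonic && i < n) {
      out <- rbind(out, data.frame(site_class = "donor", intron_index = i,
                                   label = paste0("E-", m)))
    }
    if (loc$offset5 <= acceptor_exonic && i > 1L) {
      out <- rbind(out, data.frame(site_class = "acceptor", intron_index = i - 1L,
                                   label = paste0("E+", loc$offset5)))
    }
  } else {
    j <- loc$index; M <- loc$length
    d <- loc$offset5; a <- M - d + 1L
    if (d <= donor_intronic) {
      out <- rbind(out, data.frame(site_class = "donor", intron_index = j,
                                   label = paste0("+", d)))
    }
    if (a <= acceptor_intronic) {
      out <- rbind(out, data.frame(site_class = "acceptor", intron_index = j,
                                   label = paste0("-", a)))
    }
  }
  out
}
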