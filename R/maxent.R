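## Optional plug-in for externally supplied maximum-entropy score matrices in
## the standard MaxEntScan distribution layout:
##   donor:    me2x5            (16384 values, one per 7-mer: the 9-mer minus
##                               the GT consensus positions +1/+2)
##   acceptor: me2x3acc1..9     (marginal probability tables over overlapping
##                               sub-windows of the 23-mer minus the AG)
## The package never bundles these files; point `load_maxent_models()` at a
## directory containing them (config key `maxent_dir`).

MAXENT_BGD <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
## consensus base probabilities at the canonical dinucleotide positions
ME5_CONS1 <- c(A = 0.0040, C = 0.0032, G = 0.9896, T = 0.0032)  # +1 (G)
ME5_CONS2 <- c(A = 0.0034, C = 0.0039, G = 0.0042, T = 0.9884)  # +2 (T)
ME3_CONS1 <- c(A = 0.9903, C = 0.0032, G = 0.0034, T = 0.0030)  # -2 (A)
ME3_CONS2 <- c(A = 0.0027, C = 0.0037, G = 0.9905, T = 0.0030)  # -1 (G)

## Alphabetical k-mer index (A<C<G<T, first base most significant), 1-based.
kmer_index <- function(kmer) {
  b <- chars(kmer)
  v <- match(b, c("A", "C", "G", "T")) - 1L
  sum(v * 4L^rev(seq_along(v) - 1L)) + 1L
}

read_maxent_table <- function(path, n_expected) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) != n_expected) {
    stop(sprintf("%s: expected %d values, got %d", basename(path),
                 n_expected, length(vals)))
  }
  vals
}

## Acceptor sub-windows of the 21-mer (23-mer minus the AG at -2/-1):
## numerator tables 1-5, denominator tables 6-9. start/width are 1-based.
ME3_WINDOWS <- data.frame(
  table = 1:9,
  start = c(1L, 8L, 15L, 5L, 12L, 5L, 8L, 12L, 15L),
  width = c(7L, 7L, 7L, 7L, 7L, 3L, 4L, 3L, 4L),
  sign  = c(1L, 1L, 1L, 1L, 1L, -1L, -1L, -1L, -1L)
)

#' Load maximum-entropy score matrices
#'
#' Reads a directory laid out like the published MaxEntScan distribution and
#' returns donor/acceptor `score_model`s with `model_kind = "maxent"`. Either
#' site may be absent; at least one must be present.
#'
#' @param dir directory containing `me2x5` (donor) and/or `me2x3acc1` ..
#'   `me2x3acc9` (acceptor).
#' @return list with `donor` and/or `acceptor` models.
#' @export
load_maxent_models <- function(dir) {
  if (!dir.exists(dir)) stop("maxent_dir does not exist: ", dir)
  out <- list()
  p5 <- file.path(dir, "me2x5")
  if (file.exists(p5)) {
    out$donor <- structure(list(
      model_kind = "maxent", site_type = "donor_9mer", width = DONOR_WIDTH,
      me2x5 = read_maxent_table(p5, 4L^7L),
      background = MAXENT_BGD), class = "score_model")
  }
  p3 <- file.path(dir, paste0("me2x3acc", 1:9))
  if (all(file.exists(p3))) {
    tabs <- lapply(1:9, function(i) {
      read_maxent_table(p3[i], 4L^ME3_WINDOWS$width[i])
    })
    out$acceptor <- structure(list(
      model_kind = "maxent", site_type = "acceptor_23mer",
      width = ACCEPTOR_WIDTH, tables = tabs,
      background = MAXENT_BGD), class = "score_model")
  }
  if (length(out) == 0L) {
    stop("no maxent matrix files (me2x5 / me2x3acc1..9) found in ", dir)
  }
  out
}

## Score a window under a loaded maxent model (called via score_window()).
maxent_score <- function(window, model) {
  b <- chars(window)
  if (model$site_type == "donor_9mer") {
    cons <- (ME5_CONS1[b[4]] / MAXENT_BGD[b[4]]) *
      (ME5_CONS2[b[5]] / MAXENT_BGD[b[5]])
    rest <- paste0(substr(window, 1, 3), substr(window, 6, 9))
    unname(log2(cons * model$me2x5[kmer_index(rest)]))
  } else {
    cons <- (ME3_CONS1[b[19]] / MAXENT_BGD[b[19]]) *
      (ME3_CONS2[b[20]] / MAXENT_BGD[b[20]])
    rest <- paste0(substr(window, 1, 18), substr(window, 21, 23))
    acc <- 0
    for (i in 1:9) {
      w <- ME3_WINDOWS[i, ]
      sub <- substr(rest, w$start, w$start + w$width - 1L)
      acc <- acc + w$sign * log2(model$tables[[i]][kmer_index(sub)])
    }
    unname(log2(cons) + acc)
  }
}

## Exact maximum over all windows, exploiting the factorization.
maxent_max_score <- function(model) {
  if (model$site_type == "donor_9mer") {
    cons_max <- max(outer(ME5_CONS1 / MAXENT_BGD, ME5_CONS2 / MAXENT_BGD))
    log2(cons_max * max(model$me2x5))
  } else {
    cons_max <- max(outer(ME3_CONS1 / MAXENT_BGD, ME3_CONS2 / MAXENT_BGD))
    log2(cons_max) + maxent3_rest_max(model$tables)
  }
}

## Dynamic program over the 21-mer: every term is +/- log2 p(sub-window) over
## a contiguous window of width <= 7, so a state of the trailing 6 bases is
## sufficient for exact maximization.
maxent3_rest_max <- function(tables) {
  bases <- c("A", "C", "G", "T")
  best <- 0; names(best) <- ""   # empty prefix
  for (pos in 1:21) {
    nxt <- new.env(parent = emptyenv())
    ends_here <- ME3_WINDOWS[ME3_WINDOWS$start + ME3_WINDOWS$width - 1L == pos, ,
                             drop = FALSE]
    for (si in seq_along(best)) {
      st <- names(best)[si]
      for (b in bases) {
        full <- paste0(st, b)         # trailing bases incl. current position
        sc <- best[[si]]
        for (k in seq_len(nrow(ends_here))) {
          w <- ends_here[k, ]
          sub <- substr(full, nchar(full) - w$width + 1L, nchar(full))
          sc <- sc + w$sign * log2(tables[[w$table]][kmer_index(sub)])
        }
        key <- if (nchar(full) > 6L) substr(full, nchar(full) - 5L, nchar(full)) else full
        cur <- if (exists(key, envir = nxt, inherits = FALSE)) get(key, envir = nxt) else -Inf
        if (sc > cur) assign(key, sc, envir = nxt)
      }
    }
    keys <- ls(nxt)
    best <- vapply(keys, function(k) get(k, envir = nxt), numeric(1))
    names(best) <- keys
  }
  max(best)
}
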