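#' @import data.table
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head tail
NULL

## Closed set of breakpoint varieties.  Two evidence items may only share a
## cluster when their varieties are equal.
VARIETIES <- c("DELETION", "DUPLICATION", "INVERSION", "INTERCHROM")

#' Breakpoint varieties
#'
#' The closed enumeration of SV classes assigned to a breakpoint based on the
#' orientation of its supporting evidence: `DELETION`, `DUPLICATION`
#' (tandem), `INVERSION` and `INTERCHROM` (inter-chromosomal adjacency,
#' e.g. a translocation breakend).
#'
#' @return Character vector of the four variety names.
#' @export
varieties <- function() VARIETIES

assert_variety <- function(v) {
  if (!all(v %in% VARIETIES)) {
    stop("unknown variety: ", paste(setdiff(v, VARIETIES), collapse = ", "))
  }
  v
}

#' Breakpoint probability interval
#'
#' One end of a breakpoint: a reference range (0-based, half-open) together
#' with a vector of non-negative relative probabilities, one per position.
#' Probabilities are *relative* weights; they are only normalized when a
#' cluster is finalized into a call.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; `end - start` must equal `length(p)`.
#' @param p Numeric vector of non-negative relative probabilities with at
#'   least one positive entry.
#' @return An object of class `bp_interval`.
#' @examples
#' bp_interval("chr1", 100, 110, rep(1, 10))
#' @export
bp_interval <- function(chrom, start, end, p) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start < end)) stop("bp_interval: start must be < end")
  if (length(p) != end - start) {
    stop("bp_interval: length(p) must equal end - start")
  }
  if (any(p < 0) || !any(p > 0)) {
    stop("bp_interval: p must be non-negative with at least one positive entry")
  }
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 p = as.numeric(p)),
            class = "bp_interval")
}

#' @export
print.bp_interval <- function(x, ...) {
  cat(sprintf("<bp_interval> %s:[%d,%d) n=%d max=%.4g\n",
              x$chrom, as.integer(x$start), as.integer(x$end),
              length(x$p), max(x$p)))
  invisible(x)
}

#' One item of breakpoint evidence
#'
#' A pair of breakpoint probability intervals (left and right end of the
#' putative breakpoint), a variety, a positive weight, a sample identifier
#' and the signal the evidence came from.  The left interval must not come
#' after the right one under the canonical `(chromosome, start)` order;
#' [canonicalize_evidence()] enforces this.
#'
#' @param left,right [bp_interval] objects.
#' @param variety One of [varieties()].
#' @param weight Positive evidence weight (enters thresholding, not the
#'   probability product).
#' @param sample_id Sample/instance identifier.
#' @param source One of `"READPAIR"`, `"SPLITREAD"`, `"GENERIC"`.
#' @param align_left,align_right Optional `c(start, end)` reference spans of
#'   the alignments the evidence came from (used by excluded-region
#'   filtering); default to the interval bounds.
#' @param canonicalize Swap sides so the left interval does not follow the
#'   right under `(chromosome, start)` order (default TRUE).  Channels
#'   that already know which interval belongs to the genomically first
#'   breakpoint end - e.g. read-pair evidence, where the x read maps to
#'   the left interval even when a short event makes the mate's interval
#'   start earlier - pass FALSE.
#' @return An object of class `bp_evidence`.
#' @export
bp_evidence <- function(left, right, variety, weight = 1, sample_id = "S1",
                        source = c("GENERIC", "READPAIR", "SPLITREAD"),
                        align_left = NULL, align_right = NULL,
                        canonicalize = TRUE) {
  stopifnot(inherits(left, "bp_interval"), inherits(right, "bp_interval"))
  source <- match.arg(source)
  assert_variety(variety)
  if (!(weight > 0)) stop("bp_evidence: weight must be > 0")
  e <- structure(list(left = left, right = right, variety = variety,
                      weight = as.numeric(weight),
                      sample_id = as.character(sample_id), source = source,
                      align_left = if (is.null(align_left))
                        c(left$start, left$end) else as.numeric(align_left),
                      align_right = if (is.null(align_right))
                        c(right$start, right$end) else as.numeric(align_right)),
                 class = "bp_evidence")
  if (canonicalize) canonicalize_evidence(e) else e
}

## Natural-sort chromosome ranking used for the canonical order ("chr2"
## before "chr10"); falls back to lexicographic for non-numeric suffixes.
chrom_rank_key <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub("^(chr)?", "", chrom)))
  sprintf("%020.1f|%s", ifelse(is.na(num), Inf, num), chrom)
}

chrom_lte <- function(c1, s1, c2, s2) {
  k1 <- chrom_rank_key(c1); k2 <- chrom_rank_key(c2)
  k1 < k2 | (k1 == k2 & s1 <= s2)
}

#' Put evidence in canonical left/right order
#'
#' Swaps the two intervals (and alignment spans) when the "left" interval
#' follows the "right" one under the natural-sort `(chromosome, start)`
#' order, so that inter-chromosomal evidence always has its left interval on
#' the lower-ordered chromosome.
#'
#' @param e A [bp_evidence] object.
#' @return The canonicalized `bp_evidence`.
#' @export
canonicalize_evidence <- function(e) {
  if (!chrom_lte(e$left$chrom, e$left$start, e$right$chrom, e$right$start)) {
    tmp <- e$left; e$left <- e$right; e$right <- tmp
    tmp <- e$align_left; e$align_left <- e$align_right; e$align_right <- tmp
  }
  e
}

#' @export
print.bp_evidence <- function(x, ...) {
  cat(sprintf("<bp_evidence> %s %s %s:[%d,%d) / %s:[%d,%d) w=%g sample=%s\n",
              x$source, x$variety,
              x$left$chrom, as.integer(x$left$start), as.integer(x$left$end),
              x$right$chrom, as.integer(x$right$start),
              as.integer(x$right$end), x$weight, x$sample_id))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Evidence tables: the engine's columnar representation of an evidence
## stream.  One row per evidence item; p_l / p_r are list columns holding the
## relative-probability vectors.  Shared profile vectors (read-pair evidence)
## are stored by reference, so large streams stay compact.

EVIDENCE_COLS <- c("l_chrom", "l_start", "l_end", "r_chrom", "r_start",
                   "r_end", "variety", "weight", "sample_id", "source",
                   "al_start", "al_end", "ar_start", "ar_end")

empty_evidence_table <- function() {
  data.table(l_chrom = character(), l_start = numeric(), l_end = numeric(),
             r_chrom = character(), r_start = numeric(), r_end = numeric(),
             variety = character(), weight = numeric(),
             sample_id = character(), source = character(),
             al_start = numeric(), al_end = numeric(),
             ar_start = numeric(), ar_end = numeric(),
             p_l = list(), p_r = list())
}

#' Convert evidence objects to an evidence table
#'
#' The clustering engine operates on a columnar `data.table` with one row
#' per evidence item and list columns `p_l`/`p_r` for the probability
#' vectors.  This converts a list of [bp_evidence] objects to that layout.
#'
#' @param evidence A list of [bp_evidence] objects (or a single one).
#' @return A `data.table` with one row per evidence item.
#' @export
evidence_table <- function(evidence) {
  if (inherits(evidence, "bp_evidence")) evidence <- list(evidence)
  if (length(evidence) == 0) return(empty_evidence_table())
  stopifnot(all(vapply(evidence, inherits, TRUE, "bp_evidence")))
  data.table(
    l_chrom = vapply(evidence, function(e) e$left$chrom, ""),
    l_start = vapply(evidence, function(e) e$left$start, 0),
    l_end   = vapply(evidence, function(e) e$left$end, 0),
    r_chrom = vapply(evidence, function(e) e$right$chrom, ""),
    r_start = vapply(evidence, function(e) e$right$start, 0),
    r_end   = vapply(evidence, function(e) e$right$end, 0),
    variety = vapply(evidence, function(e) e$variety, ""),
    weight  = vapply(evidence, function(e) e$weight, 0),
    sample_id = vapply(evidence, function(e) e$sample_id, ""),
    source  = vapply(evidence, function(e) e$source, ""),
    al_start = vapply(evidence, function(e) e$align_left[1], 0),
    al_end   = vapply(evidence, function(e) e$align_left[2], 0),
    ar_start = vapply(evidence, function(e) e$align_right[1], 0),
    ar_end   = vapply(evidence, function(e) e$align_right[2], 0),
    p_l = lapply(evidence, function(e) e$left$p),
    p_r = lapply(evidence, function(e) e$right$p))
}

## Vectorized counterpart of canonicalize_evidence(): swap sides on rows
## where the left interval follows the right under (chromosome, start).
canonicalize_evidence_table <- function(tab) {
  if (nrow(tab) == 0) return(tab)
  swap <- !chrom_lte(tab$l_chrom, tab$l_start, tab$r_chrom, tab$r_start)
  if (any(swap)) {
    lcols <- c("l_chrom", "l_start", "l_end", "al_start", "al_end", "p_l")
    rcols <- c("r_chrom", "r_start", "r_end", "ar_start", "ar_end", "p_r")
    tmp <- tab[swap, ..lcols]
    for (i in seq_along(lcols)) {
      data.table::set(tab, which(swap), lcols[i], tab[swap, ][[rcols[i]]])
      data.table::set(tab, which(swap), rcols[i], tmp[[lcols[i]]])
    }
  }
  tab
}

#' Convert an evidence table back to a list of evidence objects
#'
#' @param tab An evidence table as produced by [evidence_table()].
#' @return A list of [bp_evidence] objects.
#' @export
evidence_list <- function(tab) {
  if (nrow(tab) == 0) return(list())
  lapply(seq_len(nrow(tab)), function(i) {
    bp_evidence(
      bp_interval(tab$l_chrom[i], tab$l_start[i], tab$l_end[i], tab$p_l[[i]]),
      bp_interval(tab$r_chrom[i], tab$r_start[i], tab$r_end[i], tab$p_r[[i]]),
      variety = tab$variety[i], weight = tab$weight[i],
      sample_id = tab$sample_id[i], source = tab$source[i],
      align_left = c(tab$al_start[i], tab$al_end[i]),
      align_right = c(tab$ar_start[i], tab$ar_end[i]),
      canonicalize = FALSE)      # the table already fixed the sides
  })
}
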