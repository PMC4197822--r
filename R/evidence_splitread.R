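## Split-read evidence: reads aligned in two or more discontiguous segments.
## The junction between adjacent segments marks a breakpoint directly, so
## the resulting probability intervals are narrow, centered at the split and
## decaying exponentially toward their edges.

#' One aligned segment of a split read
#'
#' @param read_name Read identifier.
#' @param chrom Chromosome the segment aligned to.
#' @param orient `"+"` or `"-"`.
#' @param ref_start,ref_end 0-based half-open reference span.
#' @param query_start,query_end Half-open coordinates within the original
#'   (unreversed) read.
#' @param mapq Mapping quality.
#' @param sample_id Sample identifier.
#' @return A `split_segment` list.
#' @export
split_segment <- function(read_name, chrom, orient, ref_start, ref_end,
                          query_start, query_end, mapq = 60,
                          sample_id = "S1") {
  stopifnot(orient %in% c("+", "-"), ref_start < ref_end,
            query_start < query_end)
  structure(list(read_name = read_name, chrom = as.character(chrom),
                 orient = orient, ref_start = as.numeric(ref_start),
                 ref_end = as.numeric(ref_end),
                 query_start = as.numeric(query_start),
                 query_end = as.numeric(query_end),
                 mapq = mapq, sample_id = sample_id),
            class = "split_segment")
}

#' Split-read channel configuration
#'
#' @param v_s Half-width in bases of each breakpoint interval; an interval
#'   spans `[center - v_s, center + v_s + 1)`.  Defaults to 20 (the default
#'   `back_distance` of the read-pair channel), giving a 41-base interval.
#' @param decay_scale Bases per e-fold drop of the exponential profile;
#'   defaults to `v_s / 4`, so the tails fall to about `exp(-4)`.
#' @param min_non_overlap Minimum number of read bases covered by exactly
#'   one of the two segments (default 150).
#' @param weight Evidence weight (default 1).
#' @param min_mapping_threshold Minimum mapping quality (default 1).
#' @param sample_id Sample identifier.
#' @return A `splitread_config` list.
#' @export
splitread_config <- function(v_s = 20, decay_scale = v_s / 4,
                             min_non_overlap = 150, weight = 1,
                             min_mapping_threshold = 1, sample_id = "S1") {
  stopifnot(v_s >= 1, decay_scale > 0, weight > 0)
  structure(list(v_s = v_s, decay_scale = decay_scale,
                 min_non_overlap = min_non_overlap, weight = weight,
                 min_mapping_threshold = min_mapping_threshold,
                 sample_id = sample_id),
            class = "splitread_config")
}

#' Decompose one split read into adjacent segment pairs
#'
#' A read aligned in `n` segments yields the `n - 1` pairs of segments that
#' are adjacent in read (query) order; each pair is considered individually
#' as breakpoint evidence.
#'
#' @param segments List of [split_segment]s from one read.
#' @return List of 2-element lists `(a, b)` with `a` preceding `b` in query
#'   coordinates; empty for a contiguous (single-segment) alignment.
#' @export
enumerate_split_pairs <- function(segments) {
  if (length(segments) < 2) return(list())
  ord <- order(vapply(segments, `[[`, 0, "query_start"))
  segments <- segments[ord]
  lapply(seq_len(length(segments) - 1L), function(i) {
    list(a = segments[[i]], b = segments[[i + 1L]])
  })
}

#' Split-pair quality filters
#'
#' Requires both segments to meet the mapping-quality threshold and the
#' number of read bases covered by exactly one of the two segments to reach
#' `min_non_overlap`.  Bases in the query overlap (junction microhomology)
#' count for neither segment.
#'
#' @param pair A list `(a, b)` of [split_segment]s, `a` first in the read.
#' @param cfg A [splitread_config].
#' @return `TRUE` iff the pair passes.
#' @export
passes_split_filters <- function(pair, cfg = splitread_config()) {
  a <- pair$a; b <- pair$b
  if (a$mapq < cfg$min_mapping_threshold ||
      b$mapq < cfg$min_mapping_threshold) return(FALSE)
  la <- a$query_end - a$query_start
  lb <- b$query_end - b$query_start
  ov <- max(0, min(a$query_end, b$query_end) -
                 max(a$query_start, b$query_start))
  (la + lb - 2 * ov) >= cfg$min_non_overlap
}

#' Classify the breakpoint variety of a split pair
#'
#' With matching orientations the reference order of the two segments
#' separates deletions from tandem duplications: on the forward strand a
#' gap (`a` before `b` in the reference) indicates a deletion and reversed
#' order a tandem duplication; both rules flip when the segments align to
#' the reverse strand.  Mismatched orientations mark an inversion and
#' different chromosomes an inter-chromosomal breakpoint.
#'
#' @inheritParams passes_split_filters
#' @return A variety string.
#' @export
classify_split_variety <- function(pair) {
  a <- pair$a; b <- pair$b
  if (a$chrom != b$chrom) return("INTERCHROM")
  if (a$orient != b$orient) return("INVERSION")
  if (a$ref_start == b$ref_start)
    stop("classify_split_variety: ambiguous split (equal start coordinates)")
  forward_order <- a$ref_start < b$ref_start
  if (a$orient == "-") forward_order <- !forward_order
  if (forward_order) "DELETION" else "DUPLICATION"
}

## Exponentially decaying profile over [center - v_s, center + v_s + 1).
split_profile <- function(v_s, decay_scale) {
  exp(-abs(seq(-v_s, v_s)) / decay_scale)
}

## Breakpoint interval centers for a split pair, as c(left, right) in
## genomic order.  Deletions break at (end of the genomically first
## segment, start of the second); duplications at (start of the first,
## end of the second); inversions at matched ends or matched starts
## depending on the orientation of the query-first segment.
split_centers <- function(pair, variety) {
  a <- pair$a; b <- pair$b
  if (variety == "INTERCHROM") {
    ## per segment, the junction sits at the end adjacent to the split:
    ## the query-later side of a, the query-earlier side of b
    ca <- if (a$orient == "+") a$ref_end - 1 else a$ref_start
    cb <- if (b$orient == "+") b$ref_start else b$ref_end - 1
    return(list(chroms = c(a$chrom, b$chrom), centers = c(ca, cb)))
  }
  g1 <- if (a$ref_start <= b$ref_start) a else b    # genomically first
  g2 <- if (a$ref_start <= b$ref_start) b else a
  centers <- switch(variety,
    DELETION = c(g1$ref_end, g2$ref_start),
    DUPLICATION = c(g1$ref_start, g2$ref_end),
    INVERSION = {
      if (a$ref_start <= b$ref_start) {
        if (a$orient == "+") c(a$ref_end, b$ref_end)
        else c(a$ref_start, b$ref_start)
      } else {
        if (a$orient == "-") c(a$ref_end, b$ref_end)
        else c(a$ref_start, b$ref_start)
      }
    })
  list(chroms = c(g1$chrom, g1$chrom), centers = sort(centers))
}

#' Map a split pair to breakpoint evidence
#'
#' Both breakpoint intervals span `[center - v_s, center + v_s + 1)` with
#' probability proportional to `exp(-|i - center| / decay_scale)`: highest
#' at the split and decaying exponentially toward the edges.  Centers are
#' chosen per variety (see [classify_split_variety()] and the source);
#' left/right assignment follows the canonical chromosome/coordinate order.
#'
#' @inheritParams passes_split_filters
#' @param chrom_lengths Optional named chromosome lengths for edge clipping.
#' @return A [bp_evidence] with `source = "SPLITREAD"`.
#' @export
split_to_breakpoint_evidence <- function(pair, cfg = splitread_config(),
                                         chrom_lengths = NULL) {
  variety <- classify_split_variety(pair)
  cc <- split_centers(pair, variety)
  prof <- split_profile(cfg$v_s, cfg$decay_scale)
  mk <- function(chrom, center) {
    s <- center - cfg$v_s; e <- center + cfg$v_s + 1
    clen <- if (is.null(chrom_lengths)) Inf else unname(chrom_lengths[chrom])
    lo <- max(s, 0); hi <- min(e, clen)
    p <- prof
    if (lo > s || hi < e) p <- p[(lo - s + 1L):(length(p) - (e - hi))]
    bp_interval(chrom, lo, hi, p)
  }
  a <- pair$a; b <- pair$b
  bp_evidence(mk(cc$chroms[1], cc$centers[1]), mk(cc$chroms[2], cc$centers[2]),
              variety, weight = cfg$weight, sample_id = cfg$sample_id,
              source = "SPLITREAD",
              align_left = c(a$ref_start, a$ref_end),
              align_right = c(b$ref_start, b$ref_end))
}

## ---------------------------------------------------------------------------
## Vectorized channel: segment table -> evidence table.
## `segments` columns: read_name, chrom, orient, ref_start, ref_end,
## query_start, query_end, mapq (query coordinates already in original-read
## orientation).  Segments are grouped by read_name and decomposed into
## adjacent pairs.

splitread_evidence_table <- function(segments, cfg = splitread_config(),
                                     chrom_lengths = NULL) {
  if (nrow(segments) == 0) return(empty_evidence_table())
  segments <- segments[mapq >= cfg$min_mapping_threshold]
  setorder(segments, read_name, query_start)
  n <- nrow(segments)
  if (n < 2) return(empty_evidence_table())
  ## adjacent rows of the same read form the candidate pairs
  i <- which(segments$read_name[-n] == segments$read_name[-1])
  if (length(i) == 0) return(empty_evidence_table())
  a <- segments[i]; b <- segments[i + 1L]

  la <- a$query_end - a$query_start
  lb <- b$query_end - b$query_start
  ov <- pmax(0, pmin(a$query_end, b$query_end) -
                  pmax(a$query_start, b$query_start))
  keep <- (la + lb - 2 * ov) >= cfg$min_non_overlap &
    !(a$chrom == b$chrom & a$orient == b$orient & a$ref_start == b$ref_start)
  a <- a[keep]; b <- b[keep]
  if (nrow(a) == 0) return(empty_evidence_table())

  same_chrom <- a$chrom == b$chrom
  forward_order <- fifelse(a$orient == "-", a$ref_start > b$ref_start,
                           a$ref_start < b$ref_start)
  variety <- fifelse(!same_chrom, "INTERCHROM",
              fifelse(a$orient != b$orient, "INVERSION",
               fifelse(forward_order, "DELETION", "DUPLICATION")))

  ## centers, in genomic order for same-chromosome events
  a_first <- a$ref_start <= b$ref_start
  g1s <- fifelse(a_first, a$ref_start, b$ref_start)
  g1e <- fifelse(a_first, a$ref_end, b$ref_end)
  g2s <- fifelse(a_first, b$ref_start, a$ref_start)
  g2e <- fifelse(a_first, b$ref_end, a$ref_end)
  inv_ends <- fifelse(a_first, a$orient == "+", a$orient == "-")
  c1 <- fifelse(variety == "DELETION", g1e,
         fifelse(variety == "DUPLICATION", g1s,
          fifelse(variety == "INVERSION",
                  fifelse(inv_ends, pmin(a$ref_end, b$ref_end),
                          pmin(a$ref_start, b$ref_start)),
                  fifelse(a$orient == "+", a$ref_end - 1, a$ref_start))))
  c2 <- fifelse(variety == "DELETION", g2s,
         fifelse(variety == "DUPLICATION", g2e,
          fifelse(variety == "INVERSION",
                  fifelse(inv_ends, pmax(a$ref_end, b$ref_end),
                          pmax(a$ref_start, b$ref_start)),
                  fifelse(b$orient == "+", b$ref_start, b$ref_end - 1))))
  chrom1 <- a$chrom
  chrom2 <- b$chrom

  prof <- split_profile(cfg$v_s, cfg$decay_scale)
  clen <- function(chrom) {
    if (is.null(chrom_lengths)) rep(Inf, length(chrom))
    else unname(chrom_lengths[chrom])
  }
  side <- function(chrom, center) {
    s <- center - cfg$v_s; e <- center + cfg$v_s + 1
    lo <- pmax(s, 0); hi <- pmin(e, clen(chrom))
    p <- rep(list(prof), length(s))
    for (j in which(lo > s | hi < e)) {
      p[[j]] <- p[[j]][(lo[j] - s[j] + 1L):(length(p[[j]]) - (e[j] - hi[j]))]
    }
    list(start = lo, end = hi, p = p)
  }
  L <- side(chrom1, c1); R <- side(chrom2, c2)

  canonicalize_evidence_table(data.table(
    l_chrom = chrom1, l_start = L$start, l_end = L$end,
    r_chrom = chrom2, r_start = R$start, r_end = R$end,
    variety = variety, weight = cfg$weight,
    sample_id = cfg$sample_id, source = "SPLITREAD",
    al_start = a$ref_start, al_end = a$ref_end,
    ar_start = b$ref_start, ar_end = b$ref_end,
    p_l = L$p, p_r = R$p))
}
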