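## Read-pair evidence: discordant paired-end alignments mapped to breakpoint
## probability intervals via the empirical fragment-length distribution.

#' A read alignment
#'
#' @param chrom Chromosome name.
#' @param orient `"+"` or `"-"`.
#' @param start 0-based inclusive start of the aligned bases.
#' @param end Exclusive end.
#' @param mapq Mapping quality (default 60).
#' @param sample_id Sample identifier.
#' @return A `read_alignment` list.
#' @export
read_alignment <- function(chrom, orient, start, end, mapq = 60,
                           sample_id = "S1") {
  stopifnot(orient %in% c("+", "-"), start < end)
  structure(list(chrom = as.character(chrom), orient = orient,
                 start = as.numeric(start), end = as.numeric(end),
                 mapq = mapq, sample_id = sample_id),
            class = "read_alignment")
}

#' A canonicalized read-pair alignment
#'
#' The two ends of one sequenced fragment, ordered so that
#' `(x$chrom, x$start) <= (y$chrom, y$start)`.
#'
#' @param x,y [read_alignment] objects.
#' @param name Read name.
#' @return A `read_pair` list with the pair in canonical order.
#' @export
read_pair <- function(x, y, name = "") {
  if (!chrom_lte(x$chrom, x$start, y$chrom, y$start)) { tmp <- x; x <- y; y <- tmp }
  structure(list(x = x, y = y, name = name), class = "read_pair")
}

#' Read-pair channel configuration
#'
#' @param v_l Discordance multiplier: a same-chromosome `(+,-)` pair is
#'   concordant when its apparent length lies within `mean +/- v_l * stdev`.
#' @param v_f Interval-extent multiplier: evidence intervals extend
#'   `ceiling(mean + v_f * stdev)` bases beyond the read.
#' @param back_distance Bases by which intervals extend behind the read end,
#'   into the aligned bases (default 20).
#' @param weight Evidence weight (default 1).
#' @param min_mapping_threshold Minimum mapping quality (default 1).
#' @param sample_id Sample identifier.
#' @param discordant_z Convenience knob setting both `v_l` and `v_f`
#'   (default 4, the published run setting).
#' @return A `readpair_config` list.
#' @export
readpair_config <- function(discordant_z = 4, v_l = discordant_z,
                            v_f = discordant_z, back_distance = 20,
                            weight = 1, min_mapping_threshold = 1,
                            sample_id = "S1") {
  stopifnot(v_l > 0, v_f > 0, back_distance >= 0, weight > 0)
  structure(list(v_l = v_l, v_f = v_f, back_distance = back_distance,
                 weight = weight,
                 min_mapping_threshold = min_mapping_threshold,
                 sample_id = sample_id),
            class = "readpair_config")
}

#' Estimate a fragment library from observed fragment lengths
#'
#' Builds the sample mean, sample standard deviation and the empirical
#' survival function `D(j)` = fraction of fragments longer than `j` from
#' concordant ("properly paired") fragment lengths.  `D` is clamped to 1
#' for `j <= 0` (positions behind the read start are trivially spanned)
#' and is 0 beyond the longest observed fragment.
#'
#' @param x Numeric vector of fragment lengths, a two-column
#'   `data.frame`/`matrix` of `(length, count)`, or the path to a histogram
#'   file with one `length<TAB>count` pair per line (`#` comments allowed).
#' @param read_length Read length carried along for interval geometry
#'   (default 150).
#' @return A `fragment_library`: list with `mean`, `stdev`, `read_length`
#'   and the survival function `D`.
#' @examples
#' lib <- fragment_library(c(400, 500, 600))
#' lib$mean          # 500
#' lib$D(450)        # 2/3
#' @export
fragment_library <- function(x, read_length = 150) {
  if (is.character(x) && length(x) == 1) {
    h <- data.table::fread(x, header = FALSE, col.names = c("length", "count"))
    x <- as.matrix(h)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    lengths <- rep(x[, 1], x[, 2])
  } else {
    lengths <- as.numeric(x)
  }
  if (length(lengths) < 2) stop("fragment_library: need >= 2 fragment lengths")
  mu <- mean(lengths)
  sigma <- stats::sd(lengths)
  n <- length(lengths)
  sorted <- sort(lengths)
  maxlen <- sorted[n]
  D <- function(j) {
    ## fraction of fragments with length > j, clamped to 1 for j <= 0
    ifelse(j <= 0, 1, (n - findInterval(j, sorted)) / n)
  }
  structure(list(mean = mu, stdev = sigma, read_length = read_length,
                 max_length = maxlen, D = D, n = n,
                 cache = new.env(parent = emptyenv())),
            class = "fragment_library")
}

#' Parametric (normal) fragment library
#'
#' For use when only the mean and standard deviation of the fragment-length
#' distribution are known: the survival function is the normal upper tail,
#' clamped to 1 for `j <= 0`.
#'
#' @param mean,stdev Fragment-length mean and standard deviation.
#' @param read_length Read length (default 150).
#' @return A `fragment_library`.
#' @export
fragment_library_normal <- function(mean, stdev, read_length = 150) {
  stopifnot(mean > 0, stdev >= 0)
  D <- function(j) {
    ifelse(j <= 0, 1,
           if (stdev == 0) as.numeric(j < mean)
           else stats::pnorm(j, mean, stdev, lower.tail = FALSE))
  }
  structure(list(mean = mean, stdev = stdev, read_length = read_length,
                 max_length = mean + 10 * stdev, D = D, n = NA_integer_,
                 cache = new.env(parent = emptyenv())),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library> mean=%.1f stdev=%.2f n=%d read_length=%d\n",
              x$mean, x$stdev, x$n, as.integer(x$read_length)))
  invisible(x)
}

#' Is a read pair discordant? (the breakpoint test)
#'
#' A pair is evidence of a breakpoint when it aligns in an unexpected
#' configuration: matching orientations, switched `(-,+)` orientation,
#' different chromosomes, or an apparent fragment length
#' (`y$end - x$start`) outside `mean +/- v_l * stdev`.
#'
#' @param pair A canonicalized [read_pair].
#' @param lib A [fragment_library].
#' @param cfg A [readpair_config].
#' @return `TRUE` iff the pair is discordant.
#' @export
is_discordant <- function(pair, lib, cfg = readpair_config()) {
  x <- pair$x; y <- pair$y
  if (x$chrom != y$chrom) return(TRUE)
  if (x$orient != "+" || y$orient != "-") return(TRUE)
  len <- y$end - x$start
  len < lib$mean - cfg$v_l * lib$stdev || len > lib$mean + cfg$v_l * lib$stdev
}

#' Classify the breakpoint variety of a discordant pair
#'
#' Same chromosome: matching orientations mean an inversion, `(-,+)` a
#' tandem duplication, `(+,-)` a deletion.  Different chromosomes are
#' inter-chromosomal.  The label reflects the evidence orientation; complex
#' events may masquerade as simpler ones.
#'
#' @param pair A canonicalized [read_pair].
#' @return A variety string.
#' @export
classify_pair_variety <- function(pair) {
  x <- pair$x; y <- pair$y
  if (x$chrom != y$chrom) return("INTERCHROM")
  if (x$orient == y$orient) return("INVERSION")
  if (x$orient == "-") return("DUPLICATION")
  "DELETION"
}

## Relative-probability profile for a forward-oriented read of length rl:
## position i in [end - back, end + extent) gets D(i - start), i.e. the
## probability that the sequenced fragment was long enough for the pair to
## span i.  Within the back-distance region D is at (or near) its maximum,
## so p stays non-increasing away from the read.  The profile depends only
## on the library and (back, extent), so it is cached on the library and
## shared by reference across evidence rows.
pe_profile <- function(lib, cfg, orient = "+") {
  extent <- ceiling(lib$mean + cfg$v_f * lib$stdev)
  key <- sprintf("%d|%d|%d|%s", as.integer(lib$read_length),
                 as.integer(cfg$back_distance), as.integer(extent), orient)
  prof <- lib$cache[[key]]
  if (is.null(prof)) {
    j <- if (orient == "+") {
      ## offsets j = i - start for i in [end - back, end + extent)
      seq(lib$read_length - cfg$back_distance,
          length.out = cfg$back_distance + extent)
    } else {
      ## offsets j = end - i for i in [start - extent, start + back)
      seq(lib$read_length + extent, by = -1,
          length.out = cfg$back_distance + extent)
    }
    prof <- lib$D(j)
    prof[prof <= 0] <- 1e-12   # keep tail positions admissible, not certain
    lib$cache[[key]] <- prof
  }
  prof
}

## Breakpoint interval for one read of a discordant pair.
read_to_interval <- function(chrom, orient, start, end, lib, cfg,
                             chrom_len = Inf) {
  extent <- ceiling(lib$mean + cfg$v_f * lib$stdev)
  prof <- pe_profile(lib, cfg, orient)
  if (orient == "+") {
    s <- end - cfg$back_distance
    e <- end + extent
  } else {
    s <- start - extent
    e <- start + cfg$back_distance
  }
  ## clip at chromosome edges, never negative
  lo <- max(s, 0); hi <- min(e, chrom_len)
  if (lo > s || hi < e) prof <- prof[(lo - s + 1L):(length(prof) - (e - hi))]
  bp_interval(chrom, lo, hi, prof)
}

#' Map a discordant pair to breakpoint evidence
#'
#' Per read: a forward read yields an interval
#' `[end - back_distance, end + ceiling(mean + v_f * stdev))` with
#' probability at position `i` proportional to `D(i - start)`; a reverse
#' read mirrors this upstream of its start.  The canonical first read maps
#' to the left interval, its mate to the right; variety comes from
#' [classify_pair_variety()].
#'
#' @inheritParams is_discordant
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   clip intervals at chromosome edges.
#' @return A [bp_evidence] with `source = "READPAIR"`.
#' @export
pair_to_breakpoint_evidence <- function(pair, lib, cfg = readpair_config(),
                                        chrom_lengths = NULL) {
  x <- pair$x; y <- pair$y
  clen <- function(chrom) {
    if (is.null(chrom_lengths)) Inf else unname(chrom_lengths[chrom])
  }
  left <- read_to_interval(x$chrom, x$orient, x$start, x$end, lib, cfg,
                           clen(x$chrom))
  right <- read_to_interval(y$chrom, y$orient, y$start, y$end, lib, cfg,
                            clen(y$chrom))
  ## the pair is already in canonical read order: x maps to the left
  ## interval by convention, even when a short event makes the mate's
  ## upstream-extending interval start earlier
  bp_evidence(left, right, classify_pair_variety(pair), weight = cfg$weight,
              sample_id = cfg$sample_id, source = "READPAIR",
              align_left = c(x$start, x$end), align_right = c(y$start, y$end),
              canonicalize = FALSE)
}

## ---------------------------------------------------------------------------
## Vectorized channel: pair table -> evidence table.
## `pairs` columns: x_chrom, x_orient, x_start, x_end, x_mapq,
##                  y_chrom, y_orient, y_start, y_end, y_mapq
## (already canonicalized by (chrom, start)).

readpair_evidence_table <- function(pairs, lib, cfg = readpair_config(),
                                    chrom_lengths = NULL) {
  if (nrow(pairs) == 0) return(empty_evidence_table())
  pairs <- pairs[x_mapq >= cfg$min_mapping_threshold &
                 y_mapq >= cfg$min_mapping_threshold]
  if (nrow(pairs) == 0) return(empty_evidence_table())
  ## discard malformed mates sharing a start (apparent length <= 0)
  pairs <- pairs[!(x_chrom == y_chrom & y_end - x_start <= 0)]
  len <- pairs$y_end - pairs$x_start
  disc <- pairs$x_chrom != pairs$y_chrom |
    pairs$x_orient != "+" | pairs$y_orient != "-" |
    len < lib$mean - cfg$v_l * lib$stdev |
    len > lib$mean + cfg$v_l * lib$stdev
  pairs <- pairs[disc]
  if (nrow(pairs) == 0) return(empty_evidence_table())

  variety <- fifelse(pairs$x_chrom != pairs$y_chrom, "INTERCHROM",
              fifelse(pairs$x_orient == pairs$y_orient, "INVERSION",
               fifelse(pairs$x_orient == "-", "DUPLICATION", "DELETION")))

  extent <- ceiling(lib$mean + cfg$v_f * lib$stdev)
  prof_fwd <- pe_profile(lib, cfg, "+")
  prof_rev <- pe_profile(lib, cfg, "-")
  clen <- function(chrom) {
    if (is.null(chrom_lengths)) rep(Inf, length(chrom))
    else unname(chrom_lengths[chrom])
  }

  side <- function(chrom, orient, start, end) {
    s <- fifelse(orient == "+", end - cfg$back_distance, start - extent)
    e <- fifelse(orient == "+", end + extent, start + cfg$back_distance)
    lo <- pmax(s, 0); hi <- pmin(e, clen(chrom))
    clipped <- which(lo > s | hi < e)
    p <- vector("list", length(s))
    fwd <- orient == "+"
    p[fwd] <- list(prof_fwd); p[!fwd] <- list(prof_rev)
    for (i in clipped) {
      p[[i]] <- p[[i]][(lo[i] - s[i] + 1L):(length(p[[i]]) - (e[i] - hi[i]))]
    }
    list(start = lo, end = hi, p = p)
  }
  L <- side(pairs$x_chrom, pairs$x_orient, pairs$x_start, pairs$x_end)
  R <- side(pairs$y_chrom, pairs$y_orient, pairs$y_start, pairs$y_end)

  ## pairs arrive in canonical read order (x on the lower-ordered
  ## chromosome/coordinate), so x's interval is the left one by convention
  data.table(
    l_chrom = pairs$x_chrom, l_start = L$start, l_end = L$end,
    r_chrom = pairs$y_chrom, r_start = R$start, r_end = R$end,
    variety = variety, weight = cfg$weight,
    sample_id = cfg$sample_id, source = "READPAIR",
    al_start = pairs$x_start, al_end = pairs$x_end,
    ar_start = pairs$y_start, ar_end = pairs$y_end,
    p_l = L$p, p_r = R$p)
}
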