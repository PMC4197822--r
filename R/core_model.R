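## Core breakpoint model: interval intersection, liberal cluster merging and
## finalization of clusters into calls via the trimmed product (or sum) of
## member distributions.

#' Do two breakpoint interval ranges intersect?
#'
#' Half-open semantics: `[100,200)` and `[200,300)` do *not* intersect.
#' Accepts [bp_interval] objects or any list with `chrom`, `start`, `end`.
#'
#' @param a,b Interval bounds.
#' @return `TRUE` iff both are on the same chromosome and the ranges overlap.
#' @export
intervals_intersect <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Create a cluster from a single piece of evidence
#'
#' A cluster (itself a breakpoint) is the set of evidence corroborating one
#' breakpoint plus liberally merged bounds: per side, the arithmetic mean of
#' member starts and of member ends (floored to integers to keep half-open
#' coordinates).  Means damp the pull of outlier alignments that would
#' otherwise drag a max-start/min-end intersection away from the true
#' breakpoint.
#'
#' @param e A [bp_evidence] object.
#' @return An object of class `bp_cluster`.
#' @export
new_cluster <- function(e) {
  stopifnot(inherits(e, "bp_evidence"))
  structure(list(evidence = list(e),
                 l_chrom = e$left$chrom, r_chrom = e$right$chrom,
                 variety = e$variety,
                 sum_ls = e$left$start, sum_le = e$left$end,
                 sum_rs = e$right$start, sum_re = e$right$end,
                 n = 1L),
            class = "bp_cluster")
}

#' Merged (liberal) bounds of a cluster
#'
#' @param cluster A `bp_cluster`.
#' @return List with `left`/`right` elements, each `c(start, end)` holding
#'   the floored per-side means of member starts and ends.
#' @export
cluster_bounds <- function(cluster) {
  list(left = c(floor(cluster$sum_ls / cluster$n),
                floor(cluster$sum_le / cluster$n)),
       right = c(floor(cluster$sum_rs / cluster$n),
                 floor(cluster$sum_re / cluster$n)))
}

#' Merge one piece of evidence into a cluster
#'
#' The caller must have established that `e` intersects the cluster on both
#' sides and shares its variety; violating either is a contract error.
#'
#' @param cluster A `bp_cluster`.
#' @param e A [bp_evidence] object.
#' @return The enlarged cluster.
#' @export
merge_into_cluster <- function(cluster, e) {
  if (e$variety != cluster$variety)
    stop("merge_into_cluster: variety mismatch")
  if (e$left$chrom != cluster$l_chrom || e$right$chrom != cluster$r_chrom)
    stop("merge_into_cluster: chromosome mismatch")
  ok <- any(vapply(cluster$evidence, function(m) {
    intervals_intersect(m$left, e$left) && intervals_intersect(m$right, e$right)
  }, TRUE))
  if (!ok) stop("merge_into_cluster: evidence does not intersect the cluster")
  cluster$evidence[[length(cluster$evidence) + 1L]] <- e
  cluster$sum_ls <- cluster$sum_ls + e$left$start
  cluster$sum_le <- cluster$sum_le + e$left$end
  cluster$sum_rs <- cluster$sum_rs + e$right$start
  cluster$sum_re <- cluster$sum_re + e$right$end
  cluster$n <- cluster$n + 1L
  cluster
}

#' @export
print.bp_cluster <- function(x, ...) {
  b <- cluster_bounds(x)
  cat(sprintf("<bp_cluster> %s n=%d %s:[%d,%d) / %s:[%d,%d)\n",
              x$variety, x$n, x$l_chrom, b$left[1], b$left[2],
              x$r_chrom, b$right[1], b$right[2]))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Distribution utilities

#' Trim low-probability tail mass from a breakpoint interval
#'
#' Greedy end trimming: repeatedly remove whichever terminal position
#' (leftmost or rightmost) carries the smaller probability, as long as the
#' total removed mass stays within `1 - keep`; then renormalize.  Ties
#' remove the rightmost end, so `keep = 0` degenerates to the single
#' leftmost maximum position.
#'
#' @param interval A [bp_interval] with normalized `p`.
#' @param keep Fraction of probability mass to retain (default 0.999, i.e.
#'   drop the lowest 0.1%).
#' @return The trimmed, renormalized [bp_interval].
#' @export
trim_distribution <- function(interval, keep = 0.999) {
  stopifnot(keep >= 0, keep <= 1)
  p <- interval$p
  budget <- 1 - keep
  removed <- 0
  lo <- 1L; hi <- length(p)
  while (hi > lo) {
    if (p[hi] <= p[lo]) { cand <- p[hi]; side <- "r" }
    else { cand <- p[lo]; side <- "l" }
    if (removed + cand > budget) break
    removed <- removed + cand
    if (side == "r") hi <- hi - 1L else lo <- lo + 1L
  }
  q <- p[lo:hi]
  bp_interval(interval$chrom, interval$start + lo - 1L,
              interval$start + hi, q / sum(q))
}

#' Central credible interval of a breakpoint distribution
#'
#' Removes at most `(1 - mass)/2` probability mass from each end of the
#' distribution (never a position whose removal would drop the retained
#' mass below `mass`) and returns the genomic bounds of what is left.
#'
#' @param interval A [bp_interval] with normalized `p`.
#' @param mass Mass to retain (default 0.95).
#' @return `c(start, end)`, half-open genomic coordinates.
#' @export
confidence_interval <- function(interval, mass = 0.95) {
  p <- interval$p
  n <- length(p)
  tail_budget <- (1 - mass) / 2
  cum <- cumsum(p)
  ## largest k with sum(p[1:k]) <= budget (tolerate fp rounding)
  lo <- sum(cum <= tail_budget + 1e-12)
  rcum <- cumsum(rev(p))
  hi <- sum(rcum <= tail_budget + 1e-12)
  lo <- min(lo, n - 1L); hi <- min(hi, n - 1L - lo)
  c(interval$start + lo, interval$end - hi)
}

#' Most likely breakpoint position
#'
#' @param interval A [bp_interval].
#' @return The genomic coordinate of the leftmost maximum of `p`.
#' @export
max_position <- function(interval) {
  interval$start + which.max(interval$p) - 1L
}

## ---------------------------------------------------------------------------
## Finalization

LOG_FLOOR <- log(1e-300)

## Evaluate a member's (relative) probability vector over [s, e) given the
## member interval [ms, me) and vector p; positions outside [ms,me) get NA.
window_p <- function(p, ms, s, e) {
  idx <- (s - ms + 1L):(e - ms)
  p[idx]
}

finalize_annotate <- function(chrom_l, chrom_r, pl, pr, sup_l, sup_r,
                              members, trim_keep) {
  left  <- bp_interval(chrom_l, sup_l[1], sup_l[2], pl / sum(pl))
  right <- bp_interval(chrom_r, sup_r[1], sup_r[2], pr / sum(pr))
  left  <- trim_distribution(left, trim_keep)
  right <- trim_distribution(right, trim_keep)
  weights <- vapply(members, `[[`, 0, "weight")
  samples <- vapply(members, `[[`, "", "sample_id")
  sources <- vapply(members, `[[`, "", "source")
  structure(list(
    left = left, right = right,
    ci95_left = confidence_interval(left), ci95_right = confidence_interval(right),
    max_left = max_position(left), max_right = max_position(right),
    variety = members[[1]]$variety,
    total_weight = sum(weights),
    per_sample_support = vapply(split(weights, samples), sum, 0),
    evidence_counts = vapply(split(sources, sources), length, 0L),
    n_evidence = length(members)), class = "sv_call")
}

#' @export
print.sv_call <- function(x, ...) {
  cat(sprintf(
    "<sv_call> %s %s:[%d,%d) / %s:[%d,%d) w=%g n=%d max=(%d,%d)\n",
    x$variety, x$left$chrom, as.integer(x$left$start),
    as.integer(x$left$end), x$right$chrom, as.integer(x$right$start),
    as.integer(x$right$end), x$total_weight, x$n_evidence,
    as.integer(x$max_left), as.integer(x$max_right)))
  invisible(x)
}

## Shared driver for product/sum finalization of a list of bp_evidence.
finalize_members <- function(members, mode, trim_keep) {
  ls <- vapply(members, function(e) e$left$start, 0)
  le <- vapply(members, function(e) e$left$end, 0)
  rs <- vapply(members, function(e) e$right$start, 0)
  re <- vapply(members, function(e) e$right$end, 0)
  chrom_l <- members[[1]]$left$chrom
  chrom_r <- members[[1]]$right$chrom

  if (mode == "sum") {
    sup_l <- c(min(ls), max(le)); sup_r <- c(min(rs), max(re))
    pl <- numeric(sup_l[2] - sup_l[1]); pr <- numeric(sup_r[2] - sup_r[1])
    for (i in seq_along(members)) {
      ii <- (ls[i] - sup_l[1] + 1L):(le[i] - sup_l[1])
      pl[ii] <- pl[ii] + members[[i]]$left$p
      jj <- (rs[i] - sup_r[1] + 1L):(re[i] - sup_r[1])
      pr[jj] <- pr[jj] + members[[i]]$right$p
    }
    return(finalize_annotate(chrom_l, chrom_r, pl, pr, sup_l, sup_r,
                             members, trim_keep))
  }

  ## product: common support is [max start, min end) per side
  sup_l <- c(max(ls), min(le)); sup_r <- c(max(rs), min(re))
  if (sup_l[1] < sup_l[2] && sup_r[1] < sup_r[2]) {
    logl <- numeric(sup_l[2] - sup_l[1])
    logr <- numeric(sup_r[2] - sup_r[1])
    for (i in seq_along(members)) {
      logl <- logl + pmax(log(window_p(members[[i]]$left$p, ls[i],
                                       sup_l[1], sup_l[2])), LOG_FLOOR)
      logr <- logr + pmax(log(window_p(members[[i]]$right$p, rs[i],
                                       sup_r[1], sup_r[2])), LOG_FLOOR)
    }
    pl <- exp(logl - max(logl)); pr <- exp(logr - max(logr))
    all_floor <- max(logl) <= length(members) * LOG_FLOOR + 1e-9 ||
      max(logr) <= length(members) * LOG_FLOOR + 1e-9
    if (!all_floor) {
      return(finalize_annotate(chrom_l, chrom_r, pl, pr, sup_l, sup_r,
                               members, trim_keep))
    }
  }
  NULL
}

## Fallback for empty/zero product support: locate the leftmost peak of the
## member-distribution sum on each side, drop members whose interval does not
## contain that point, and retry on the survivors.
product_fallback <- function(members, trim_keep) {
  repeat {
    sum_call <- finalize_members(members, "sum", trim_keep = 1)
    peak_l <- max_position(sum_call$left)
    peak_r <- max_position(sum_call$right)
    keep <- vapply(members, function(e) {
      e$left$start <= peak_l && peak_l < e$left$end &&
        e$right$start <= peak_r && peak_r < e$right$end
    }, TRUE)
    if (all(keep)) {
      ## all survivors contain both peaks: the product over them is
      ## positive at the peaks, so finalize_members must succeed
      res <- finalize_members(members, "product", trim_keep)
      if (is.null(res)) stop("finalize_product: fallback failed to converge")
      return(res)
    }
    if (!any(keep)) stop("finalize_product: fallback removed all evidence")
    members <- members[keep]
  }
}

#' Finalize a cluster as the trimmed product of its member distributions
#'
#' Per side the call support is `[max of member starts, min of member
#' ends)`; the call distribution is the per-position product of member
#' probabilities over that support (computed in log space with a floor of
#' 1e-300 per factor), normalized, then trimmed with [trim_distribution()].
#' If the liberal merge admitted members whose intervals do not jointly
#' overlap (empty or all-zero product), the fallback applies: the leftmost
#' maximum of the member-distribution *sum* is located per side, members not
#' containing those points are discarded, and the product is recomputed on
#' the survivors.
#'
#' @param cluster A `bp_cluster` (or list of [bp_evidence]).
#' @param trim_keep Mass fraction retained by trimming (default 0.999).
#' @return An `sv_call` with trimmed, normalized distributions, 95%
#'   credible intervals, maximum positions, per-sample support and
#'   per-source evidence counts.
#' @export
finalize_product <- function(cluster, trim_keep = 0.999) {
  members <- cluster_members(cluster)
  res <- finalize_members(members, "product", trim_keep)
  if (is.null(res)) res <- product_fallback(members, trim_keep)
  res
}

#' Finalize a cluster as the trimmed mixture (sum) of member distributions
#'
#' Per side the support is `[min of member starts, max of member ends)` and
#' the distribution the position-wise sum of member probabilities: the value
#' at a position reflects the level of agreement among the evidence.  Less
#' precise than the product but robust for low-quality data.
#'
#' @inheritParams finalize_product
#' @return An `sv_call`.
#' @export
finalize_sum <- function(cluster, trim_keep = 0.999) {
  finalize_members(cluster_members(cluster), "sum", trim_keep)
}

cluster_members <- function(cluster) {
  members <- if (inherits(cluster, "bp_cluster")) cluster$evidence else cluster
  if (length(members) == 0) stop("finalize: empty cluster")
  members
}
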