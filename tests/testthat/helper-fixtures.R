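## Shared fixtures and independent oracles.  The oracles deliberately use
## naive algorithms (direct per-position arithmetic, union-find closure)
## so they stay independent of the implementation paths they check.

uniform_interval <- function(chrom, start, end) {
  bp_interval(chrom, start, end, rep(1, end - start))
}

uniform_evidence <- function(ls, le, rs, re, variety = "DELETION",
                             weight = 1, sample_id = "S1",
                             chrom = "chr1", rchrom = chrom) {
  bp_evidence(uniform_interval(chrom, ls, le),
              uniform_interval(rchrom, rs, re),
              variety = variety, weight = weight, sample_id = sample_id)
}

## random evidence whose left/right intervals all contain anchor points,
## guaranteeing a non-empty product support
random_overlapping_cluster <- function(n, max_len = 50, anchor_l = 1000,
                                       anchor_r = 5000) {
  lapply(seq_len(n), function(i) {
    ls <- anchor_l - sample.int(max_len %/% 2, 1)
    le <- anchor_l + sample.int(max_len %/% 2, 1)
    rs <- anchor_r - sample.int(max_len %/% 2, 1)
    re <- anchor_r + sample.int(max_len %/% 2, 1)
    bp_evidence(bp_interval("chr1", ls, le, runif(le - ls, 0.05, 1)),
                bp_interval("chr1", rs, re, runif(re - rs, 0.05, 1)),
                variety = "DELETION", weight = 1,
                sample_id = sample(c("A", "B"), 1))
  })
}

## brute-force trimmed-product oracle: direct per-position multiplication
## over the max-start/min-end support, then normalization (no log space)
oracle_product <- function(members) {
  ls <- vapply(members, function(e) e$left$start, 0)
  le <- vapply(members, function(e) e$left$end, 0)
  rs <- vapply(members, function(e) e$right$start, 0)
  re <- vapply(members, function(e) e$right$end, 0)
  one_side <- function(starts, ends, side) {
    s <- max(starts); e <- min(ends)
    if (s >= e) return(NULL)
    p <- rep(1, e - s)
    for (k in seq_along(members)) {
      q <- members[[k]][[side]]$p
      for (pos in seq_len(e - s)) {
        p[pos] <- p[pos] * q[(s - starts[k]) + pos]
      }
    }
    if (sum(p) == 0) return(NULL)
    list(start = s, end = e, p = p / sum(p))
  }
  list(left = one_side(ls, le, "left"), right = one_side(rs, re, "right"))
}

## union-find transitive-closure clustering oracle (ignores streaming)
oracle_clusters <- function(tab) {
  n <- nrow(tab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (tab$variety[i] == tab$variety[j] &&
        tab$l_chrom[i] == tab$l_chrom[j] &&
        tab$r_chrom[i] == tab$r_chrom[j] &&
        tab$l_start[i] < tab$l_end[j] && tab$l_start[j] < tab$l_end[i] &&
        tab$r_start[i] < tab$r_end[j] && tab$r_start[j] < tab$r_end[i]) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(split(seq_len(n), roots))
}

## greedy credible-interval oracle: walk in from each end, never removing
## more than the per-tail budget
oracle_ci <- function(p, start, mass = 0.95) {
  budget <- (1 - mass) / 2
  lo <- 1; removed <- 0
  while (lo < length(p) && removed + p[lo] <= budget + 1e-12) {
    removed <- removed + p[lo]; lo <- lo + 1
  }
  hi <- length(p); removed <- 0
  while (hi > lo && removed + p[hi] <= budget + 1e-12) {
    removed <- removed + p[hi]; hi <- hi - 1
  }
  c(start + lo - 1, start + hi)
}

## small deterministic sim for engine-level tests
small_deletion_sim <- function(n_del = 1, coverage = 20, seed = 11,
                               genome = 1e6, size_range = c(400, 600)) {
  cfg <- sim_config(chrom_lengths = c(chr1 = genome), n_del = n_del,
                    size_range = size_range, coverage = coverage,
                    seed = seed)
  sim <- simulate_variants(cfg)
  aln <- simulate_alignments(sim$blocks, sim$alt_lengths, cfg)
  list(cfg = cfg, sim = sim, aln = aln)
}
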